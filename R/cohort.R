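#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed directly from group means, SDs and
#' sizes (as printed in cohort characteristic tables), with Satterthwaite
#' degrees of freedom.
#'
#' @param mean1,sd1,n1 first group summary (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @return A list: `t`, `df` (Satterthwaite), `p` (two-sided).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("negative SD", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2)
      stop("undefined statistic: both SDs zero and means equal",
           call. = FALSE)
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with 1 degree of freedom; the Yates continuity
#' correction is applied by default, as is conventional for 2x2 tables of
#' cohort characteristics.
#'
#' @param a,b first row (e.g. cases: exposed, unexposed).
#' @param c,d second row (e.g. controls).
#' @param continuity apply the Yates correction (default TRUE).
#' @return A list: `chi2`, `df` (1), `p`.
#' @export
chisq_2x2 <- function(a, b, c, d, continuity = TRUE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  check_margins(tab)
  ct <- suppressWarnings(chisq.test(tab, correct = continuity))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

check_margins <- function(tab) {
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin", call. = FALSE)
  invisible(tab)
}

#' Chi-square test of an r x c contingency table
#'
#' Pearson chi-square without continuity correction on `(r-1)(c-1)`
#' degrees of freedom.  When any expected count falls below 5 the
#' asymptotic p-value is unreliable, so a Monte-Carlo p-value (permutation
#' of the table under fixed margins) is additionally reported; seed the
#' RNG before calling for reproducibility.
#'
#' @param tab an r x c matrix of counts (r, c >= 2).
#' @param mc_reps Monte-Carlo replicates when triggered (default 1e5).
#' @param force_mc compute the Monte-Carlo p-value regardless of the
#'   expected counts (default FALSE).
#' @return A list: `chi2`, `df`, `p` (asymptotic), `p_mc` (Monte-Carlo,
#'   or `NA` when not computed), `min_expected`.
#' @export
chisq_rxc <- function(tab, mc_reps = 1e5, force_mc = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  check_margins(tab)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  p_mc <- NA_real_
  if (force_mc || any(ct$expected < 5))
    p_mc <- suppressWarnings(
      chisq.test(tab, correct = FALSE, simulate.p.value = TRUE,
                 B = mc_reps))$p.value
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, p_mc = p_mc, min_expected = min(ct$expected))
}

#' Case/control characteristic table from a dataset
#'
#' Two-sample comparisons of the covariates between cases and controls:
#' Welch t for the continuous rows (age, BMI, and — descriptively — each
#' ancestry proportion), Yates-corrected chi-square for the 2x2
#' categorical rows (sex, smoking).  Summaries print as `mean (sd)` or
#' `count (percent)` with percentages within group to 1 decimal place.
#'
#' @param dataset a [dosage_dataset()] (only the samples are used).
#' @return A data.frame (schema `cohort`): `label, test, case_summary,
#'   control_summary, p`.
#' @export
cohort_table <- function(dataset) {
  s <- dataset$samples
  case <- s[s$status == "case", ]
  ctrl <- s[s$status == "control", ]
  if (nrow(case) < 2 || nrow(ctrl) < 2)
    stop("need at least 2 cases and 2 controls", call. = FALSE)

  cont_row <- function(label, x_case, x_ctrl, digits = 1) {
    w <- welch_t(mean(x_case), stats::sd(x_case), length(x_case),
                 mean(x_ctrl), stats::sd(x_ctrl), length(x_ctrl))
    data.frame(label = label, test = "welch_t",
               case_summary = sprintf("%.*f (%.*f)", digits, mean(x_case),
                                      digits, stats::sd(x_case)),
               control_summary = sprintf("%.*f (%.*f)", digits,
                                         mean(x_ctrl), digits,
                                         stats::sd(x_ctrl)),
               p = w$p, stringsAsFactors = FALSE)
  }
  cat_row <- function(label, case_yes, ctrl_yes) {
    n1 <- nrow(case); n2 <- nrow(ctrl)
    ct <- chisq_2x2(case_yes, n1 - case_yes, ctrl_yes, n2 - ctrl_yes)
    data.frame(label = label, test = "chisq_yates",
               case_summary = sprintf("%d (%.1f%%)", case_yes,
                                      100 * case_yes / n1),
               control_summary = sprintf("%d (%.1f%%)", ctrl_yes,
                                         100 * ctrl_yes / n2),
               p = ct$p, stringsAsFactors = FALSE)
  }
  out <- rbind(
    cont_row("Age", case$age, ctrl$age),
    cat_row("Gender (male)", sum(case$sex == "male"),
            sum(ctrl$sex == "male")),
    cont_row("BMI", case$bmi, ctrl$bmi),
    cat_row("Smoking (smoker)", sum(case$smoking == "smoker"),
            sum(ctrl$smoking == "smoker")),
    cont_row("Ancestry EAS", case$eas, ctrl$eas, digits = 2),
    cont_row("Ancestry SAS", case$sas, ctrl$sas, digits = 2),
    cont_row("Ancestry EUR", case$eur, ctrl$eur, digits = 2),
    cont_row("Ancestry AFR", case$afr, ctrl$afr, digits = 2))
  rownames(out) <- NULL
  out
}

#' Cohort comparisons from printed summary statistics
#'
#' Recomputes two-sample tests from a summary file rather than raw data —
#' the form in which published cohort tables are available.  The file is
#' tab- or comma-separated with columns `label, type` and, per row type:
#' `continuous` rows use `case_mean, case_sd, case_n, control_mean,
#' control_sd, control_n` (Welch t); `categorical2` rows use `case_yes,
#' case_no, control_yes, control_no` (Yates chi-square).
#'
#' @param path path to the summary file, or a data.frame of the same
#'   shape.
#' @return A data.frame: `label, test, statistic, df, p`.
#' @export
cohort_from_summary <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path))
      stop("summary file not found: ", path, call. = FALSE)
    header <- readLines(path, n = 1L)
    if (!nzchar(header)) stop("empty summary file", call. = FALSE)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  } else raw <- as.data.frame(path)
  if (!all(c("label", "type") %in% names(raw)))
    stop("summary file must have 'label' and 'type' columns",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    if (r$type == "continuous") {
      need <- c("case_mean", "case_sd", "case_n", "control_mean",
                "control_sd", "control_n")
      if (!all(need %in% names(r)) || anyNA(r[need]))
        stop("continuous row '", r$label, "' is missing summary fields",
             call. = FALSE)
      w <- welch_t(r$case_mean, r$case_sd, r$case_n,
                   r$control_mean, r$control_sd, r$control_n)
      data.frame(label = r$label, test = "welch_t", statistic = w$t,
                 df = w$df, p = w$p, stringsAsFactors = FALSE)
    } else if (r$type == "categorical2") {
      need <- c("case_yes", "case_no", "control_yes", "control_no")
      if (!all(need %in% names(r)) || anyNA(r[need]))
        stop("categorical2 row '", r$label, "' is missing cell counts",
             call. = FALSE)
      ct <- chisq_2x2(r$case_yes, r$case_no, r$control_yes, r$control_no)
      data.frame(label = r$label, test = "chisq_yates",
                 statistic = ct$chi2, df = ct$df, p = ct$p,
                 stringsAsFactors = FALSE)
    } else stop("unknown row type '", r$type, "' for label '", r$label,
                "'", call. = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
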