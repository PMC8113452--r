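#' Maximum-likelihood logistic regression
#'
#' Newton-Raphson/IRLS fit of a binary-outcome logistic model, the
#' workhorse behind the per-variant association scan.  Convergence when
#' the maximum absolute score falls below `tol_score` or the relative
#' log-likelihood change falls below `tol_ll`; the covariance is the
#' inverse observed information at the optimum.  Perfect or quasi-perfect
#' separation (diverging coefficients with a non-vanishing score) is
#' flagged as non-convergence rather than an error.
#'
#' @param y binary outcome vector (0/1).
#' @param X design matrix including an intercept column.
#' @param tol_score score convergence tolerance (default 1e-8).
#' @param tol_ll relative log-likelihood tolerance (default 1e-10).
#' @param max_iter maximum Newton iterations (default 100).
#' @return A list: `coefficients`, `vcov`, `loglik`, `converged`,
#'   `separated`, `iterations`.
#' @export
fit_logistic <- function(y, X, tol_score = 1e-8, tol_ll = 1e-10,
                         max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("more columns than observations", call. = FALSE)
  is_const <- apply(X, 2, function(col) diff(range(col)) == 0)
  has_intercept <- any(is_const & X[1, ] != 0)
  if (!has_intercept)
    stop("design matrix must include an intercept column", call. = FALSE)
  if (sum(is_const) > 1L)
    stop("constant non-intercept column in design", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  fit <- .irls_logistic(X, y, tol_score, tol_ll, max_iter)
  fit$coefficients <- as.vector(fit$coefficients)
  names(fit$coefficients) <- colnames(X)
  fit
}

# covariate design for the scan: intercept + requested covariates.
# sex -> male indicator, smoking -> smoker indicator; continuous
# covariates standardized (mean 0, SD 1) for conditioning -- this leaves
# the dosage effect and its Wald test unchanged.
build_covariate_matrix <- function(samples, covariates,
                                   standardize = TRUE) {
  cols <- list()
  for (cv in covariates) {
    x <- switch(cv,
      sex = as.numeric(samples$sex == "male"),
      smoking = as.numeric(samples$smoking == "smoker"),
      age = samples$age, bmi = samples$bmi,
      eas = samples$eas, sas = samples$sas, eur = samples$eur,
      afr = samples$afr,
      stop("unknown covariate: ", cv, call. = FALSE))
    if (diff(range(x)) == 0)
      stop("covariate '", cv, "' is constant across samples",
           call. = FALSE)
    if (standardize && cv %in% c("age", "bmi", "eas", "sas", "eur", "afr"))
      x <- (x - mean(x)) / stats::sd(x)
    cols[[cv]] <- x
  }
  cbind(`(Intercept)` = rep(1, nrow(samples)), do.call(cbind, cols))
}

#' Covariate-adjusted marginal association scan
#'
#' Fits `status ~ intercept + dosage + covariates` by maximum-likelihood
#' logistic regression for every variant and reports the Wald test of the
#' dosage effect.  Default covariates follow standard admixed-GWAS
#' practice: sex, age, BMI, smoking, and the ancestry proportions with the
#' dominant component (EAS) dropped to avoid the sum-to-one collinearity.
#' Missing dosages are mean-imputed per variant before fitting.
#'
#' @param dataset a QC-filtered [dosage_dataset()].
#' @param covariates character vector of covariate names among
#'   `sex, age, bmi, smoking, eas, sas, eur, afr`.
#' @return A data.frame (schema `assoc`), one row per variant in dataset
#'   order: `vid, chrom, pos, ref, alt, maf, beta, se, z, p, or_, n,
#'   converged`.  Non-converged (e.g. separated or monomorphic) fits have
#'   `NA` statistics and `converged = FALSE`.
#' @export
scan_associations <- function(dataset,
                              covariates = c("sex", "age", "bmi", "smoking",
                                             "sas", "eur", "afr")) {
  stopifnot(inherits(dataset, "dosage_dataset"))
  y <- as.numeric(dataset$samples$status == "case")
  if (length(unique(y)) < 2L)
    stop("all samples have the same status", call. = FALSE)
  C <- build_covariate_matrix(dataset$samples, covariates)
  n <- nrow(C)
  Q <- qr.Q(qr(C))
  dos <- mean_impute_dosages(dataset$dosages)
  m <- ncol(dos)
  X <- cbind(C[, 1, drop = FALSE], dosage = 0, C[, -1, drop = FALSE])

  maf <- beta <- se <- z <- p <- rep(NA_real_, m)
  converged <- logical(m)
  for (j in seq_len(m)) {
    d <- dos[, j]
    maf[j] <- min(mean(d) / 2, 1 - mean(d) / 2)
    if (diff(range(d)) == 0) next  # monomorphic: unusable, not an error
    res <- d - Q %*% crossprod(Q, d)
    if (sum(res^2) <= 1e-10 * sum(d^2))
      stop("dosage of variant '", dataset$variants$vid[j],
           "' is collinear with the covariates", call. = FALSE)
    X[, 2] <- d
    fit <- .irls_logistic(X, y, 1e-8, 1e-10, 100L)
    converged[j] <- fit$converged
    if (fit$converged) {
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(fit$vcov[2, 2])
      z[j] <- beta[j] / se[j]
      p[j] <- 2 * pnorm(-abs(z[j]))
    }
  }
  v <- dataset$variants
  out <- data.frame(vid = v$vid, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, maf = maf,
                    beta = beta, se = se, z = z, p = p,
                    or_ = exp(beta), n = n, converged = converged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genome-wide significant subset of a scan
#'
#' @param results an assoc data.frame from [scan_associations()].
#' @param alpha significance threshold, strict (default the historical
#'   genome-wide value 5e-8).
#' @return The rows with `p < alpha`, sorted by ascending p.
#' @export
flag_genome_wide <- function(results, alpha = 5e-8) {
  hit <- !is.na(results$p) & results$p < alpha
  out <- results[hit, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replication lookup of previously reported risk variants
#'
#' Matches each catalog entry against the scan by identifier (falling back
#' to chromosome + position) and flags evidence of replication at
#' `p < 0.05` (strict).  The effect is re-signed to the catalog risk
#' allele when that allele equals the scan's ref or alt; otherwise the
#' orientation is marked unknown.  Entries absent from the scan are
#' reported with a reason: `"filtered"` when the variant exists in the
#' supplied pre-QC dataset, `"not-genotyped"` otherwise.
#'
#' @param results an assoc data.frame.
#' @param catalog a [known_variant_catalog()].
#' @param dataset optional pre-QC [dosage_dataset()], used only to
#'   attribute missing entries.
#' @param alpha replication threshold (default 0.05).
#' @return A data.frame (schema `replication`), one row per catalog entry.
#' @export
replicate_known <- function(results, catalog, dataset = NULL,
                            alpha = 0.05) {
  key_res <- paste(results$chrom, results$pos)
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    entry <- catalog[i, ]
    j <- match(entry$vid, results$vid)
    if (is.na(j)) j <- match(paste(entry$chrom, entry$pos), key_res)
    base <- data.frame(vid = entry$vid, chrom = entry$chrom,
                       pos = entry$pos, risk_allele = entry$risk_allele,
                       source = entry$source, stringsAsFactors = FALSE)
    if (is.na(j)) {
      reason <- "not-genotyped"
      if (!is.null(dataset) &&
          (entry$vid %in% dataset$variants$vid ||
           paste(entry$chrom, entry$pos) %in%
             paste(dataset$variants$chrom, dataset$variants$pos)))
        reason <- "filtered"
      return(cbind(base, data.frame(
        found = FALSE, reason = reason, beta = NA_real_, se = NA_real_,
        p = NA_real_, or_ = NA_real_, orientation = NA_character_,
        flagged = FALSE, stringsAsFactors = FALSE)))
    }
    r <- results[j, ]
    beta <- r$beta; or_ <- r$or_
    orientation <-
      if (is.na(beta)) NA_character_
      else if (entry$risk_allele == r$alt) "risk=alt"
      else if (entry$risk_allele == r$ref) { beta <- -beta; or_ <- 1 / or_
                                             "risk=ref (effect re-signed)" }
      else "unknown"
    cbind(base, data.frame(
      found = TRUE, reason = "", beta = beta, se = r$se, p = r$p,
      or_ = or_, orientation = orientation,
      flagged = !is.na(r$p) && r$p < alpha, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract a region of scan results around a center variant
#'
#' The table regional association plots are drawn from: all scan rows on
#' the center's chromosome within `flank` base pairs of its position,
#' sorted by position.
#'
#' @param results an assoc data.frame.
#' @param center_vid identifier of the center variant (must be in
#'   `results`).
#' @param flank half-window width in bp (default 100 kb).
#' @return The region rows of `results`, sorted by position.
#' @export
region_extract <- function(results, center_vid, flank = 1e5) {
  j <- match(center_vid, results$vid)
  if (is.na(j))
    stop("center variant '", center_vid, "' not present in results",
         call. = FALSE)
  ctr <- results[j, ]
  inside <- results$chrom == ctr$chrom &
    abs(results$pos - ctr$pos) <= flank
  out <- results[inside, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
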