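#' Minor allele frequency of a dosage column
#'
#' The alternate-allele frequency is `mean(dosage)/2` over non-missing
#' entries; the MAF folds it to `min(f, 1 - f)`.
#'
#' @param dosage numeric dosages in \[0, 2\]; `NA` allowed.
#' @return MAF in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) == 0L)
    stop("MAF undefined: all dosages missing", call. = FALSE)
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Variant-level quality-control filters
#'
#' Applies the pre-analysis variant filters sequentially: first remove
#' imputed variants with imputation quality strictly below `impq_min`
#' (genotyped variants, which carry no quality score, always pass), then
#' remove variants with minor allele frequency strictly below `maf_min`.
#' Both thresholds are strict, so boundary values are retained.  MAF is
#' computed on the pooled analysis sample (cases and controls together).
#'
#' @param dataset a [dosage_dataset()].
#' @param impq_min imputation-quality threshold (default 0.3).
#' @param maf_min MAF threshold (default 0.01, i.e. 1%).
#' @return A list: `dataset` (filtered, order preserved) and `report`
#'   (class `qc_report`: input/removed/retained counts and thresholds,
#'   with each removed variant attributed to the first filter it failed).
#' @export
apply_qc <- function(dataset, impq_min = 0.3, maf_min = 0.01) {
  stopifnot(inherits(dataset, "dosage_dataset"))
  v <- dataset$variants
  fail_impq <- v$is_imputed & !is.na(v$impq) & v$impq < impq_min
  maf <- apply(dataset$dosages, 2, minor_allele_frequency)
  fail_maf <- !fail_impq & maf < maf_min
  keep <- !fail_impq & !fail_maf
  report <- structure(list(
    n_input = nrow(v),
    n_removed_impq = sum(fail_impq),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    impq_min = impq_min, maf_min = maf_min), class = "qc_report")
  if (!any(keep))
    message("QC removed every variant (", nrow(v), " input)")
  list(dataset = subset_dataset(dataset, variants = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "variants in;",
      x$n_removed_impq, "removed by imputation quality <", x$impq_min, ";",
      x$n_removed_maf, "removed by MAF <", x$maf_min, ";",
      x$n_retained, "retained\n")
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(n_input = x$n_input, n_removed_impq = x$n_removed_impq,
             n_removed_maf = x$n_removed_maf, n_retained = x$n_retained,
             impq_min = x$impq_min, maf_min = x$maf_min)
}
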