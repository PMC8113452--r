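#' Construct a variant annotation table
#'
#' One row per variant: chromosome, 1-based position, identifier, alleles,
#' and (for imputed variants) the imputation-quality score in \[0, 1\].
#' Genotyped variants carry `impq = NA` and `is_imputed = FALSE`.
#'
#' @param chrom chromosome labels (character).
#' @param pos 1-based positions (integer).
#' @param vid variant identifiers (rsID or chrom:pos:ref:alt); must be unique.
#' @param ref,alt reference / alternate allele strings.
#' @param impq imputation quality in \[0, 1\], or `NA` for genotyped variants.
#' @param is_imputed logical; defaults to `!is.na(impq)`.
#' @return A `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, vid, ref, alt, impq = NA_real_,
                          is_imputed = !is.na(impq)) {
  n <- length(chrom)
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  vid = as.character(vid), ref = as.character(ref),
                  alt = as.character(alt),
                  impq = rep_len(as.numeric(impq), n),
                  is_imputed = rep_len(as.logical(is_imputed), n),
                  stringsAsFactors = FALSE)
  validate_variant_table(v)
  class(v) <- c("variant_table", "data.frame")
  v
}

validate_variant_table <- function(v) {
  if (any(v$pos < 1L)) stop("variant positions must be >= 1", call. = FALSE)
  bad_q <- !is.na(v$impq) & (v$impq < 0 | v$impq > 1)
  if (any(bad_q))
    stop("imputation quality outside [0, 1] for: ",
         paste(v$vid[bad_q], collapse = ", "), call. = FALSE)
  if (anyDuplicated(v$vid))
    stop("duplicate variant identifiers: ",
         paste(unique(v$vid[duplicated(v$vid)]), collapse = ", "),
         call. = FALSE)
  invisible(v)
}

#' Construct a sample covariate table
#'
#' One row per sample: disease status, sex, age, BMI, smoking status, and
#' estimated ancestry proportions for the four reference super-populations
#' (EAS, SAS, EUR, AFR), which must sum to one.
#'
#' @param sid sample identifiers; must be unique.
#' @param status `"case"` or `"control"`.
#' @param sex `"female"` or `"male"`.
#' @param age age in years (non-negative).
#' @param bmi body mass index in kg/m^2 (positive).
#' @param smoking `"smoker"` or `"non-smoker"`.
#' @param eas,sas,eur,afr ancestry proportions, each in \[0, 1\], summing
#'   to 1 within `sum_tol`.
#' @param sum_tol tolerance on the ancestry sum (default 1e-6).
#' @return A `data.frame` with class `sample_table`.
#' @export
sample_table <- function(sid, status, sex, age, bmi, smoking,
                         eas, sas, eur, afr, sum_tol = 1e-6) {
  s <- data.frame(sid = as.character(sid),
                  status = match_vocab(status, c("case", "control"), "status"),
                  sex = match_vocab(sex, c("female", "male"), "sex"),
                  age = as.numeric(age), bmi = as.numeric(bmi),
                  smoking = match_vocab(smoking, c("smoker", "non-smoker"),
                                        "smoking"),
                  eas = as.numeric(eas), sas = as.numeric(sas),
                  eur = as.numeric(eur), afr = as.numeric(afr),
                  stringsAsFactors = FALSE)
  validate_sample_table(s, sum_tol = sum_tol)
  class(s) <- c("sample_table", "data.frame")
  s
}

# case-insensitive controlled-vocabulary parser; accepts "_"/" " for "-"
match_vocab <- function(x, vocab, what) {
  canon <- gsub("[ _]", "-", tolower(trimws(as.character(x))))
  ok <- canon %in% vocab
  if (!all(ok))
    stop("unrecognized ", what, " value(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (expected one of: ", paste(vocab, collapse = ", "), ")",
         call. = FALSE)
  canon
}

validate_sample_table <- function(s, sum_tol = 1e-6) {
  if (anyDuplicated(s$sid))
    stop("duplicate sample identifiers: ",
         paste(unique(s$sid[duplicated(s$sid)]), collapse = ", "),
         call. = FALSE)
  if (any(s$age < 0)) stop("negative age", call. = FALSE)
  if (any(s$bmi <= 0)) stop("non-positive BMI", call. = FALSE)
  anc <- as.matrix(s[, c("eas", "sas", "eur", "afr")])
  if (any(anc < 0 | anc > 1))
    stop("ancestry proportions must lie in [0, 1]", call. = FALSE)
  dev <- abs(rowSums(anc) - 1)
  if (any(dev > sum_tol))
    stop("ancestry proportions do not sum to 1 for sample(s): ",
         paste(s$sid[dev > sum_tol], collapse = ", "), call. = FALSE)
  invisible(s)
}

#' Construct a dosage dataset
#'
#' The central container of the pipeline: an n-samples by m-variants matrix
#' of alternate-allele dosages in \[0, 2\] (NA = missing), with aligned
#' sample covariates and variant annotations.
#'
#' @param samples a [sample_table()].
#' @param variants a [variant_table()].
#' @param dosages numeric matrix, `nrow(samples)` x `nrow(variants)`;
#'   entries in \[0, 2\] or `NA`.
#' @return An object of class `dosage_dataset`.
#' @export
dosage_dataset <- function(samples, variants, dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(samples) || ncol(dosages) != nrow(variants))
    stop("dosage matrix is ", nrow(dosages), " x ", ncol(dosages),
         " but there are ", nrow(samples), " samples and ",
         nrow(variants), " variants", call. = FALSE)
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  dimnames(dosages) <- list(samples$sid, variants$vid)
  structure(list(samples = samples, variants = variants, dosages = dosages),
            class = "dosage_dataset")
}

#' @export
print.dosage_dataset <- function(x, ...) {
  cat("dosage_dataset:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  cases:", sum(x$samples$status == "case"),
      " controls:", sum(x$samples$status == "control"), "\n")
  cat("  imputed variants:", sum(x$variants$is_imputed),
      " missing dosages:", sum(is.na(x$dosages)), "\n")
  invisible(x)
}

#' @export
dim.dosage_dataset <- function(x) dim(x$dosages)

#' Subset a dosage dataset by variant or sample index
#'
#' @param dataset a `dosage_dataset`.
#' @param variants indices (integer/logical) into the variant table, or NULL.
#' @param samples indices into the sample table, or NULL.
#' @return The restricted `dosage_dataset`.
#' @export
subset_dataset <- function(dataset, variants = NULL, samples = NULL) {
  v <- dataset$variants; s <- dataset$samples; d <- dataset$dosages
  if (!is.null(variants)) {
    v <- v[variants, , drop = FALSE]
    d <- d[, variants, drop = FALSE]
  }
  if (!is.null(samples)) {
    s <- s[samples, , drop = FALSE]
    d <- d[samples, , drop = FALSE]
  }
  rownames(v) <- NULL; rownames(s) <- NULL
  dosage_dataset(s, v, d)
}

#' Construct a known-variant catalog
#'
#' Catalog of previously reported risk variants to re-test in the scan
#' (replication lookup): identifier, location, risk allele, and a free-text
#' source label.
#'
#' @param vid variant identifiers; unique.
#' @param chrom,pos genomic location.
#' @param risk_allele the previously reported risk allele.
#' @param source provenance label (default `""`).
#' @return A `data.frame` with class `known_variant_catalog`.
#' @export
known_variant_catalog <- function(vid, chrom, pos, risk_allele, source = "") {
  k <- data.frame(vid = as.character(vid), chrom = as.character(chrom),
                  pos = as.integer(pos),
                  risk_allele = as.character(risk_allele),
                  source = as.character(source), stringsAsFactors = FALSE)
  if (anyDuplicated(k$vid))
    stop("duplicate catalog identifiers", call. = FALSE)
  class(k) <- c("known_variant_catalog", "data.frame")
  k
}

#' Mean-impute missing dosages per variant
#'
#' Missing entries of each variant column are replaced by the column mean
#' of the observed dosages (standard GWAS practice); a per-variant flag of
#' whether imputation occurred is attached as attribute `"imputed_cols"`.
#'
#' @param dosages numeric dosage matrix.
#' @return The completed matrix.
#' @export
mean_impute_dosages <- function(dosages) {
  nas <- is.na(dosages)
  touched <- colSums(nas) > 0L
  if (any(touched)) {
    for (j in which(touched)) {
      m <- mean(dosages[, j], na.rm = TRUE)
      if (is.nan(m))
        stop("variant column ", j, " is entirely missing", call. = FALSE)
      dosages[nas[, j], j] <- m
    }
  }
  attr(dosages, "imputed_cols") <- touched
  dosages
}
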