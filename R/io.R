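#' Read genotype dosages from a VCF file
#'
#' Reads per-genotype alternate-allele dosages (imputation-server style)
#' from a VCF, one column per sample.  Biallelic records only: multiallelic
#' records are skipped with a warning by default.  When the dosage FORMAT
#' tag is absent for a record, hard genotypes (`GT`) are converted to
#' dosages 0/1/2.  Per-variant imputation quality is read from an INFO tag
#' when present; variants without it are treated as directly genotyped.
#'
#' @param path path to a VCF (v4.x) file.
#' @param dosage_field FORMAT tag holding the dosage (default `"DS"`).
#' @param impq_field INFO tag holding imputation quality (default `"R2"`).
#' @param multiallelic `"skip"` (default, warns per record) or `"error"`.
#' @return A list with `variants` (a [variant_table()], file order) and
#'   `dosages` (samples x variants numeric matrix), plus `sample_ids`.
#' @export
read_vcf_dosages <- function(path, dosage_field = "DS", impq_field = "R2",
                             multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path))
    stop("cannot read VCF: file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L)
    stop("VCF contains no variant records: ", path, call. = FALSE)

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at: ",
           paste(fix[multi, "CHROM"], fix[multi, "POS"], sep = ":",
                 collapse = ", "), call. = FALSE)
    for (i in which(multi))
      warning("skipping multiallelic record ", fix[i, "CHROM"], ":",
              fix[i, "POS"], " (ALT=", alt[i], ")", call. = FALSE)
  }

  ds <- tryCatch(
    vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE),
    error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  n_rec <- nrow(fix)
  sample_ids <- colnames(vcf@gt)[-1]
  n_smp <- length(sample_ids)

  if (is.null(ds)) ds <- matrix(NA_real_, n_rec, n_smp)
  dos <- matrix(NA_real_, nrow = n_smp, ncol = n_rec)
  for (i in seq_len(n_rec)) {
    if (multi[i]) next
    di <- ds[i, ]
    if (all(is.na(di))) {
      if (is.null(gt) || all(is.na(gt[i, ])))
        stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " has neither '", dosage_field, "' nor GT", call. = FALSE)
      di <- gt_to_dosage(gt[i, ])
    }
    dos[, i] <- as.numeric(di)
  }

  impq <- rep(NA_real_, n_rec)
  if (!is.null(impq_field)) {
    q <- tryCatch(
      suppressWarnings(
        vcfR::extract.info(vcf, element = impq_field, as.numeric = TRUE)),
      error = function(e) rep(NA_real_, n_rec))
    if (length(q) == n_rec) impq <- as.numeric(q)
  }

  keep <- !multi
  vid <- fix[, "ID"]
  blank <- is.na(vid) | vid == "." | vid == ""
  vid[blank] <- paste(fix[blank, "CHROM"], fix[blank, "POS"],
                      fix[blank, "REF"], alt[blank], sep = ":")
  variants <- variant_table(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    vid = vid[keep], ref = fix[keep, "REF"], alt = alt[keep],
    impq = impq[keep])
  dosages <- dos[, keep, drop = FALSE]
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$vid
  list(variants = variants, dosages = dosages, sample_ids = sample_ids)
}

# "0/1", "1|1", "./." -> 1, 2, NA (count of '1' alleles)
gt_to_dosage <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a sample covariate table
#'
#' Delimited text (tab or comma, auto-detected from the header line) with
#' required columns `sid, status, sex, age, bmi, smoking, eas, sas, eur,
#' afr`.  Categorical values are parsed case-insensitively
#' (case/control, female/male, smoker/non-smoker).
#'
#' @param path path to the covariate file.
#' @param sum_tol tolerance on each row's ancestry sum (default 1e-3,
#'   accommodating rounded proportions).
#' @return A [sample_table()] in file order.
#' @export
read_covariates <- function(path, sum_tol = 1e-3) {
  if (!file.exists(path))
    stop("cannot read covariates: file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  req <- c("sid", "status", "sex", "age", "bmi", "smoking",
           "eas", "sas", "eur", "afr")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("covariate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sample_table(raw$sid, raw$status, raw$sex, raw$age, raw$bmi, raw$smoking,
               raw$eas, raw$sas, raw$eur, raw$afr, sum_tol = sum_tol)
}

#' Read a known-variant catalog
#'
#' Tab- or comma-separated with columns `vid, chrom, pos, risk_allele`
#' and optional `source`.
#'
#' @param path path to the catalog file.
#' @return A [known_variant_catalog()].
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path))
    stop("cannot read catalog: file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  req <- c("vid", "chrom", "pos", "risk_allele")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  known_variant_catalog(raw$vid, raw$chrom, raw$pos, raw$risk_allele,
                        source = if ("source" %in% names(raw)) raw$source
                                 else "")
}

#' Join genotypes and covariates into an analysis dataset
#'
#' Restricts both sides to the samples present in each (the intersection),
#' preserving the VCF sample order; the counts of dropped samples are
#' reported via `message()`.
#'
#' @param variants a [variant_table()] from [read_vcf_dosages()].
#' @param dosages samples x variants dosage matrix.
#' @param samples a [sample_table()].
#' @param sample_order VCF sample identifiers, in VCF column order.
#' @return A [dosage_dataset()].
#' @export
join_dataset <- function(variants, dosages, samples, sample_order) {
  keep <- sample_order[sample_order %in% samples$sid]
  if (length(keep) == 0L)
    stop("no samples shared between genotypes and covariates", call. = FALSE)
  drop_vcf <- length(sample_order) - length(keep)
  drop_cov <- nrow(samples) - length(keep)
  if (drop_vcf > 0L || drop_cov > 0L)
    message("join: dropped ", drop_vcf, " genotyped and ", drop_cov,
            " covariate-only sample(s); ", length(keep), " retained")
  idx <- match(keep, sample_order)
  smp <- samples[match(keep, samples$sid), , drop = FALSE]
  rownames(smp) <- NULL
  dosage_dataset(smp, variants, dosages[idx, , drop = FALSE])
}

# registered result-table schemas: required leading columns per schema
result_schemas <- function() {
  list(
    assoc = c("vid", "chrom", "pos", "ref", "alt", "maf", "beta", "se",
              "z", "p", "or_", "n", "converged"),
    screen = c("vid", "log10_bf", "rank", "selected"),
    model = c("description", "chrom", "pos", "gene", "ref", "maf",
              "estimate"),
    cohort = c("label", "test", "case_summary", "control_summary", "p"),
    replication = c("vid", "chrom", "pos", "risk_allele", "source",
                    "found", "reason", "beta", "se", "p", "or_",
                    "orientation", "flagged"),
    region = c("vid", "chrom", "pos", "ref", "alt", "maf", "beta", "se",
               "z", "p", "or_", "n", "converged"),
    qc = c("n_input", "n_removed_impq", "n_removed_maf", "n_retained",
           "impq_min", "maf_min"),
    truth = c("vid", "beta_true", "freq_true"))
}

#' Write a result table
#'
#' Tab-separated with a header row; numeric columns written at full double
#' precision (17 significant digits) so that a write/read round-trip through
#' [read_result_table()] is lossless.
#'
#' @param rows a data.frame conforming to a registered schema.
#' @param path output path.
#' @param schema one of `"assoc"`, `"screen"`, `"model"`, `"cohort"`,
#'   `"replication"`, `"region"`, `"qc"`, `"truth"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path, schema) {
  schemas <- result_schemas()
  if (!schema %in% names(schemas))
    stop("unknown result schema: '", schema, "' (registered: ",
         paste(names(schemas), collapse = ", "), ")", call. = FALSE)
  req <- schemas[[schema]]
  missing_cols <- setdiff(req, names(rows))
  if (length(missing_cols))
    stop("rows do not conform to schema '", schema, "': missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- as.data.frame(rows)[, req, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @inheritParams write_result_table
#' @return A data.frame with the schema's columns, numerics restored.
#' @export
read_result_table <- function(path, schema) {
  schemas <- result_schemas()
  if (!schema %in% names(schemas))
    stop("unknown result schema: '", schema, "'", call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  req <- schemas[[schema]]
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("file does not conform to schema '", schema, "': missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw
}
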