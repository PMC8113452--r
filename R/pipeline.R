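#' Default pipeline settings
#'
#' The stage parameters of the end-to-end analysis, overridable per run:
#' QC thresholds, scan covariates and genome-wide threshold, replication
#' threshold, screening size/prior/mode, joint-model covariates and GDP
#' grid.
#'
#' @return A named list.
#' @export
default_settings <- function() {
  list(impq_min = 0.3, maf_min = 0.01,
       scan_covariates = c("sex", "age", "bmi", "smoking",
                           "sas", "eur", "afr"),
       alpha_genome_wide = 5e-8, alpha_replication = 0.05,
       screen_k = 200, screen_prior_w = 0.25, screen_mode = "wakefield",
       model_covariates = c("sex", "age", "bmi", "smoking"),
       gdp_grid = default_gdp_grid(), em_tol = 1e-8, em_max_iter = 500)
}

merge_settings <- function(settings) {
  s <- default_settings()
  unknown <- setdiff(names(settings), names(s))
  if (length(unknown))
    stop("unknown setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  s[names(settings)] <- settings
  if (!is.data.frame(s$gdp_grid)) {
    if (!all(c("alpha", "eta") %in% names(s$gdp_grid)))
      stop("gdp_grid must provide alpha and eta", call. = FALSE)
    s$gdp_grid <- expand.grid(alpha = unlist(s$gdp_grid$alpha),
                              eta = unlist(s$gdp_grid$eta))
  }
  stopifnot(s$impq_min >= 0, s$impq_min <= 1, s$maf_min >= 0,
            s$maf_min <= 0.5, s$alpha_genome_wide > 0,
            s$alpha_replication > 0, s$screen_k >= 1,
            s$screen_prior_w >= 0)
  s
}

#' Run the full analysis on an in-memory dataset
#'
#' Orchestrates the stages in order: variant QC, covariate-adjusted
#' marginal scan, genome-wide flagging, known-variant replication lookup
#' (when a catalog is supplied), Bayes-factor screening, sparse polygenic
#' GDP fit with BIC hyperparameter selection, model report, and the
#' case/control characteristic table.
#'
#' @param dataset a [dosage_dataset()].
#' @param catalog optional [known_variant_catalog()].
#' @param settings named list overriding [default_settings()].
#' @param annotation optional gene-interval annotation for the model
#'   report.
#' @return A list: `qc_report`, `assoc`, `genome_wide`, `replication`
#'   (or NULL), `screen`, `model` (the selected `polygenic_model`),
#'   `model_path` (BIC path), `model_table`, `cohort`, `settings`.
#' @export
analyze_dataset <- function(dataset, catalog = NULL, settings = list(),
                            annotation = NULL) {
  s <- merge_settings(settings)
  stage <- "qc"
  out <- tryCatch({
    qc <- apply_qc(dataset, impq_min = s$impq_min, maf_min = s$maf_min)
    stage <- "scan"
    assoc <- scan_associations(qc$dataset, covariates = s$scan_covariates)
    gw <- flag_genome_wide(assoc, alpha = s$alpha_genome_wide)
    stage <- "replicate"
    repl <- if (!is.null(catalog))
      replicate_known(assoc, catalog, dataset, alpha = s$alpha_replication)
    stage <- "screen"
    scr <- screen_variants(qc$dataset, K = s$screen_k,
                           prior_w = s$screen_prior_w,
                           mode = s$screen_mode,
                           covariates = s$model_covariates)
    stage <- "fit-prs"
    sel <- fit_polygenic(qc$dataset, scr$vid[scr$selected],
                         covariates = s$model_covariates,
                         grid = s$gdp_grid, tol = s$em_tol,
                         max_iter = s$em_max_iter)
    stage <- "report"
    tab <- model_report(sel$best, qc$dataset, annotation = annotation)
    stage <- "cohort"
    coh <- cohort_table(dataset)
    list(qc_report = qc$report, qc_dataset = qc$dataset, assoc = assoc,
         genome_wide = gw, replication = repl, screen = scr,
         model = sel$best, model_path = sel$path, model_table = tab,
         cohort = coh, settings = s)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

#' Write a sample covariate table as TSV
#'
#' @param samples a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(samples, path) {
  out <- as.data.frame(samples)
  for (j in c("age", "bmi", "eas", "sas", "eur", "afr"))
    out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write its files
#'
#' Runs [simulate_cohort()] and writes the genotypes as a VCF (DS/R2
#' fields), the covariates as TSV, and the generator truth as TSV.
#'
#' @param config a [sim_config()] (its `seed` drives all randomness).
#' @param dir output directory (created if absent).
#' @return Named list of the three file paths plus the in-memory
#'   `dataset` and `truth`, invisibly.
#' @export
run_simulation <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(config)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                covariates = file.path(dir, "covariates.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_synthetic_vcf(sim$dataset, paths$vcf)
  write_covariates(sim$dataset$samples, paths$covariates)
  write_truth_table(sim$truth, paths$truth)
  invisible(c(paths, sim))
}

settings_hash <- function(s) {
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  f <- tempfile()
  writeLines(as.character(js), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the full analysis from files on disk
#'
#' Reads genotypes (VCF with dosages), covariates (TSV/CSV) and an
#' optional known-variant catalog, joins them, runs [analyze_dataset()],
#' and writes every stage's table plus a machine-readable run manifest
#' (package version, settings, settings hash, seed) to `out_dir`.
#'
#' @param vcf_path,covariates_path,catalog_path input files
#'   (`catalog_path` may be NULL).
#' @param out_dir output directory (created if absent).
#' @param settings named list overriding [default_settings()].
#' @param seed integer seed recorded in the manifest and set before the
#'   (Monte-Carlo-free, but tie-sensitive) analysis for reproducibility.
#' @return The [analyze_dataset()] result, invisibly.
#' @export
analyze_files <- function(vcf_path, covariates_path, catalog_path = NULL,
                          out_dir = ".", settings = list(), seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  geno <- read_vcf_dosages(vcf_path)
  samples <- read_covariates(covariates_path)
  catalog <- if (!is.null(catalog_path)) read_known_variants(catalog_path)
  dataset <- join_dataset(geno$variants, geno$dosages, samples,
                          geno$sample_ids)
  res <- analyze_dataset(dataset, catalog = catalog, settings = settings)

  write_result_table(as.data.frame(res$qc_report),
                     file.path(out_dir, "qc_report.tsv"), "qc")
  write_result_table(res$assoc, file.path(out_dir, "assoc.tsv"), "assoc")
  if (!is.null(res$replication))
    write_result_table(res$replication,
                       file.path(out_dir, "replication.tsv"),
                       "replication")
  write_result_table(res$screen, file.path(out_dir, "screen.tsv"),
                     "screen")
  write_result_table(res$model_table, file.path(out_dir, "model.tsv"),
                     "model")
  write_result_table(res$cohort, file.path(out_dir, "cohort.tsv"),
                     "cohort")
  manifest <- list(
    package = "polygdp",
    version = as.character(utils::packageVersion("polygdp")),
    seed = seed,
    settings = res$settings[setdiff(names(res$settings), "gdp_grid")],
    gdp_grid = res$settings$gdp_grid,
    settings_hash = settings_hash(res$settings),
    model = list(alpha = res$model$alpha, eta = res$model$eta,
                 df = res$model$df, loglik = res$model$loglik,
                 bic = res$model$bic))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
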