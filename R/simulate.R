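#' Configuration for the synthetic case-control generator
#'
#' Defaults emulate a small admixed case-control colorectal-cancer study:
#' 84 cases and 89 controls, imputed dosage genotypes in blocks of
#' AR(1)-correlated linkage disequilibrium, 57% male, age about 52 (14)
#' years, BMI about 23 (3.5) kg/m^2, smoking enriched in cases and BMI
#' lower in cases, and ancestry proportions concentrated on the East Asian
#' component.
#'
#' @param n_case,n_control target case and control counts.
#' @param m_variants number of variants.
#' @param block_size variants per LD block.
#' @param rho within-block AR(1) latent correlation, in \[0, 1).
#' @param maf_range allele-frequency bounds `(low, high)`,
#'   `0 < low <= high < 0.5`.
#' @param causal_ids integer indices (1-based) of causal variants.
#' @param causal_betas log-odds per alternate-allele dosage unit, one per
#'   causal variant.
#' @param covariate_effects named log-odds for `sex` (male vs female),
#'   `age` (per SD), `bmi` (per SD), `smoking` (smoker vs non-smoker).
#' @param intercept baseline log-odds of disease.
#' @param sex_male_prob population probability of male sex.
#' @param age_mean,age_sd,bmi_mean,bmi_sd population moments of the
#'   continuous covariates (age truncated at 18 years, BMI at 10 kg/m^2);
#'   also the standardization constants inside the risk model.
#' @param smoking_prob population smoking prevalence (case enrichment
#'   arises from a positive smoking effect).
#' @param ancestry_conc Dirichlet concentration for (EAS, SAS, EUR, AFR).
#' @param impq_range simulated imputation-quality bounds.
#' @param draw_budget maximum population draws before accrual fails.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 84, n_control = 89,
                       m_variants = 1000, block_size = 10, rho = 0.5,
                       maf_range = c(0.05, 0.45),
                       causal_ids = integer(0), causal_betas = numeric(0),
                       covariate_effects = c(sex = 0, age = 0.25,
                                             bmi = -0.9, smoking = 1.3),
                       intercept = -2.5,
                       sex_male_prob = 0.57,
                       age_mean = 52, age_sd = 14,
                       bmi_mean = 23, bmi_sd = 3.5,
                       smoking_prob = 0.25,
                       ancestry_conc = c(18.4, 1.4, 0.2, 0.02) * 5,
                       impq_range = c(0.7, 1.0),
                       draw_budget = 400 * (n_case + n_control),
                       seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high < 0.5", call. = FALSE)
  if (length(causal_ids) != length(causal_betas))
    stop("causal_ids and causal_betas lengths differ", call. = FALSE)
  if (length(causal_ids) &&
      (min(causal_ids) < 1 || max(causal_ids) > m_variants))
    stop("causal_ids out of range 1..m_variants", call. = FALSE)
  req <- c("sex", "age", "bmi", "smoking")
  if (!all(req %in% names(covariate_effects)))
    stop("covariate_effects must name sex, age, bmi, smoking",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# one haplotype: latent AR(1) gaussian within blocks, thresholded at the
# normal quantile of each variant's allele frequency
sim_haplotype <- function(n, freqs, block_size, rho) {
  m <- length(freqs)
  lat <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if ((j - 1) %% block_size == 0) next  # new block: independent
      lat[, j] <- rho * lat[, j - 1] + s * lat[, j]
    }
  }
  thr <- qnorm(freqs)
  sweep(lat, 2, thr, "<") + 0
}

sim_dosage_matrix <- function(n, freqs, block_size, rho) {
  sim_haplotype(n, freqs, block_size, rho) +
    sim_haplotype(n, freqs, block_size, rho)
}

sim_variant_table <- function(config, freqs) {
  m <- config$m_variants
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  impq <- runif(m, config$impq_range[1], config$impq_range[2])
  variant_table(chrom = rep("1", m), pos = 100000L + (seq_len(m) - 1L) * 2000L,
                vid = sprintf("snp%05d", seq_len(m)),
                ref = ref, alt = alt, impq = impq)
}

#' Simulate dosage genotypes with block LD
#'
#' Genotypes arise from a Gaussian-copula threshold model: per haplotype a
#' latent standard-normal vector with AR(1) correlation `rho^|i-j|` within
#' each block (independent across blocks) is thresholded at the normal
#' quantile of the variant's allele frequency; the dosage is the sum of two
#' independent haplotypes, so Hardy-Weinberg holds by construction.
#'
#' @param config a [sim_config()].
#' @param n number of samples (default `n_case + n_control`).
#' @return A list: `dosages` (n x m integer matrix), `variants`
#'   (a [variant_table()] with simulated imputation qualities), and
#'   `freqs` (the per-variant alternate-allele frequencies drawn from
#'   `maf_range`).
#' @export
simulate_genotypes <- function(config, n = config$n_case + config$n_control) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  freqs <- runif(config$m_variants, config$maf_range[1], config$maf_range[2])
  variants <- sim_variant_table(config, freqs)
  dosages <- sim_dosage_matrix(n, freqs, config$block_size, config$rho)
  colnames(dosages) <- variants$vid
  list(dosages = dosages, variants = variants, freqs = freqs)
}

rdirichlet_mat <- function(n, conc) {
  g <- matrix(rgamma(n * length(conc), shape = conc), n, length(conc),
              byrow = TRUE)
  g / rowSums(g)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a retrospective case-control cohort with known truth
#'
#' Draws covariates and genotypes for a source population, assigns disease
#' status from a logistic model (continuous covariates standardized by
#' their population moments), and accumulates samples until the case and
#' control quotas are both met — retrospective sampling, so the realized
#' study intercept is not the population baseline.
#'
#' @param config a [sim_config()].
#' @return A list: `dataset` (a [dosage_dataset()] with exactly
#'   `n_case` cases and `n_control` controls) and `truth` (a
#'   `truth_record`: per-variant true betas with exact zeros for
#'   non-causal variants, covariate effects, intercept, realized
#'   population prevalence, and realized allele frequencies).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$m_variants
  freqs <- runif(m, config$maf_range[1], config$maf_range[2])
  variants <- sim_variant_table(config, freqs)

  beta_true <- numeric(m)
  beta_true[config$causal_ids] <- config$causal_betas
  eff <- config$covariate_effects

  n_target <- config$n_case + config$n_control
  acc <- list(); n_acc_case <- 0L; n_acc_ctrl <- 0L
  total_draws <- 0L; total_cases <- 0L
  batch <- max(200L, as.integer(ceiling(1.5 * n_target)))

  while (n_acc_case < config$n_case || n_acc_ctrl < config$n_control) {
    if (total_draws >= config$draw_budget)
      stop("accrual budget of ", config$draw_budget, " population draws ",
           "exhausted with ", n_acc_case, "/", config$n_case, " cases and ",
           n_acc_ctrl, "/", config$n_control, " controls; adjust the ",
           "intercept toward a less extreme baseline risk", call. = FALSE)
    nb <- min(batch, config$draw_budget - total_draws)
    male <- rbinom(nb, 1, config$sex_male_prob)
    age <- rnorm_trunc(nb, config$age_mean, config$age_sd, 18)
    bmi <- rnorm_trunc(nb, config$bmi_mean, config$bmi_sd, 10)
    smoke <- rbinom(nb, 1, config$smoking_prob)
    dos <- sim_dosage_matrix(nb, freqs, config$block_size, config$rho)
    anc <- rdirichlet_mat(nb, config$ancestry_conc)

    lp <- config$intercept + eff[["sex"]] * male +
      eff[["age"]] * (age - config$age_mean) / config$age_sd +
      eff[["bmi"]] * (bmi - config$bmi_mean) / config$bmi_sd +
      eff[["smoking"]] * smoke
    if (length(config$causal_ids))
      lp <- lp + as.vector(dos[, config$causal_ids, drop = FALSE] %*%
                             config$causal_betas)
    status <- rbinom(nb, 1, plogis(lp))
    total_draws <- total_draws + nb
    total_cases <- total_cases + sum(status)

    take <- (status == 1 & n_acc_case + cumsum(status == 1) <=
               config$n_case) |
            (status == 0 & n_acc_ctrl + cumsum(status == 0) <=
               config$n_control)
    if (any(take)) {
      acc[[length(acc) + 1L]] <- list(
        male = male[take], age = age[take], bmi = bmi[take],
        smoke = smoke[take], status = status[take],
        dos = dos[take, , drop = FALSE], anc = anc[take, , drop = FALSE])
      n_acc_case <- n_acc_case + sum(status[take] == 1)
      n_acc_ctrl <- n_acc_ctrl + sum(status[take] == 0)
    }
  }

  male <- unlist(lapply(acc, `[[`, "male"))
  age <- unlist(lapply(acc, `[[`, "age"))
  bmi <- unlist(lapply(acc, `[[`, "bmi"))
  smoke <- unlist(lapply(acc, `[[`, "smoke"))
  status <- unlist(lapply(acc, `[[`, "status"))
  dos <- do.call(rbind, lapply(acc, `[[`, "dos"))
  anc <- do.call(rbind, lapply(acc, `[[`, "anc"))

  n <- length(status)
  samples <- sample_table(
    sid = sprintf("S%04d", seq_len(n)),
    status = ifelse(status == 1, "case", "control"),
    sex = ifelse(male == 1, "male", "female"),
    age = age, bmi = bmi,
    smoking = ifelse(smoke == 1, "smoker", "non-smoker"),
    eas = anc[, 1], sas = anc[, 2], eur = anc[, 3], afr = anc[, 4])
  colnames(dos) <- variants$vid
  dataset <- dosage_dataset(samples, variants, dos)
  truth <- structure(list(
    beta = setNames(beta_true, variants$vid),
    causal_ids = config$causal_ids,
    covariate_effects = eff,
    intercept = config$intercept,
    prevalence = total_cases / total_draws,
    freqs = setNames(freqs, variants$vid),
    n_population_draws = total_draws), class = "truth_record")
  list(dataset = dataset, truth = truth)
}

#' Write a dosage dataset as a VCF file
#'
#' Emits VCFv4.2 text with a `DS` FORMAT field holding the dosages and an
#' `R2` INFO field holding the imputation quality (omitted for genotyped
#' variants), readable by [read_vcf_dosages()].  Values are written at full
#' double precision so the round-trip is exact.
#'
#' @param dataset a [dosage_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "dosage_dataset"))
  v <- dataset$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polygdp synthetic cohort generator",
    paste0("##INFO=<ID=R2,Number=1,Type=Float,",
           "Description=\"Imputation quality\">"),
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples$sid), collapse = "\t")), con)
  if (nrow(v) > 0L) {
    num <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 17,
                                                     format = "g"))
    info <- ifelse(is.na(v$impq), ".", paste0("R2=", num(v$impq)))
    ds <- apply(dataset$dosages, 2, num)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = 1)  # single sample
    lines <- paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", info,
                   "DS", apply(ds, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write the generator's ground truth as a TSV
#'
#' @param truth a `truth_record` from [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  rows <- data.frame(vid = names(truth$beta), beta_true = truth$beta,
                     freq_true = truth$freqs, stringsAsFactors = FALSE)
  write_result_table(rows, path, "truth")
}
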