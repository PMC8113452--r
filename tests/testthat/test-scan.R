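test_that("logistic ML matches closed forms", {
  # intercept only: logit of the observed proportion
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_logistic(y, matrix(1, 100, 1))
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), log(30 / 70), tolerance = 1e-8)

  # binary exposure: the 2x2 log odds ratio (a=30 b=20 c=20 d=30)
  x <- rep(c(1, 0, 1, 0), c(30, 20, 20, 30))
  y <- rep(c(1, 1, 0, 0), c(30, 20, 20, 30))
  f2 <- fit_logistic(y, cbind(1, x))
  expect_equal(unname(f2$coefficients[2]), log((30 * 30) / (20 * 20)),
               tolerance = 1e-8)
})

test_that("separation is flagged, bad designs error", {
  x <- c(seq(-3, -1, length.out = 20), seq(1, 3, length.out = 20))
  y <- rep(c(0, 1), each = 20)
  f <- fit_logistic(y, cbind(1, x))
  expect_false(f$converged)
  expect_true(f$separated)

  expect_error(fit_logistic(y, cbind(x)), "intercept")
  expect_error(fit_logistic(y, cbind(1, x, x)), "rank deficient")
  expect_error(fit_logistic(y, cbind(1, x, 2)), "constant non-intercept")
  expect_error(fit_logistic(y[1:3], cbind(1, x[1:3], x[1:3]^2, x[1:3]^3)),
               "observations")
})

test_that("fitter agrees with the reference GLM on random data", {
  for (s in 1:5) {
    d <- rand_logit_data(n = 120, p = 4, seed = 300 + s)
    mine <- fit_logistic(d$y, d$X)
    ref <- stats::glm.fit(d$X, d$y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-12))
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
  }
})

test_that("scan reports covariate-adjusted Wald tests per variant", {
  cfg <- sim_config(n_case = 100, n_control = 100, m_variants = 50,
                    causal_ids = 7, causal_betas = 1.1, seed = 31)
  sim <- simulate_cohort(cfg)
  a <- scan_associations(sim$dataset)
  expect_equal(nrow(a), 50)
  ok <- a$converged
  expect_true(all(abs(a$or_[ok] - exp(a$beta[ok])) < 1e-12))
  expect_true(all(a$p[ok] > 0 & a$p[ok] <= 1))
  expect_equal(a$p[ok], 2 * pnorm(-abs(a$z[ok])), tolerance = 1e-12)
  # the planted variant is the top hit here
  expect_equal(which.min(a$p), 7L)
})

test_that("|z| is invariant to affine rescaling of continuous covariates", {
  cfg <- sim_config(n_case = 80, n_control = 80, m_variants = 10,
                    seed = 37)
  sim <- simulate_cohort(cfg)
  a1 <- scan_associations(sim$dataset)
  sim$dataset$samples$age <- sim$dataset$samples$age * 10 + 5
  a2 <- scan_associations(sim$dataset)
  expect_equal(a1$z, a2$z, tolerance = 1e-6)
})

test_that("binary dosage with no covariates collapses to the table log-OR", {
  d <- rep(c(1, 0, 1, 0), c(35, 25, 15, 45))
  status <- rep(c("case", "case", "control", "control"),
                c(35, 25, 15, 45))
  ds <- make_dataset(cbind(d), status = status)
  a <- scan_associations(ds, covariates = character(0))
  expect_equal(a$beta, log((35 * 45) / (25 * 15)), tolerance = 1e-6)
})

test_that("degenerate scan designs raise named errors", {
  cfg <- sim_config(n_case = 40, n_control = 40, m_variants = 5, seed = 41)
  sim <- simulate_cohort(cfg)
  sim$dataset$samples$sex <- rep("male", 80)
  expect_error(scan_associations(sim$dataset), "'sex'")

  # dosage column identical to an included covariate
  sim2 <- simulate_cohort(cfg)
  smoke <- as.numeric(sim2$dataset$samples$smoking == "smoker")
  sim2$dataset$dosages[, 3] <- smoke
  expect_error(scan_associations(sim2$dataset), "collinear")
})

test_that("genome-wide flagging is strict and sorted", {
  res <- data.frame(vid = c("a", "b", "c", "d"),
                    p = c(1e-9, 5e-8, 2e-10, 1e-4))
  out <- flag_genome_wide(res)
  expect_identical(out$vid, c("c", "a"))  # 5e-8 tie excluded (strict <)
  expect_identical(flag_genome_wide(data.frame(vid = "x", p = 1e-4))$vid,
                   character(0))
})

test_that("replication lookup flags, re-orients, and explains misses", {
  res <- data.frame(
    vid = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 300L), ref = c("A", "C", "G"),
    alt = c("G", "T", "A"), maf = 0.2,
    beta = c(0.78, -0.5, 0.3), se = 0.3, z = c(2.6, -1.67, 1),
    p = c(0.009, 0.05, 0.3), or_ = exp(c(0.78, -0.5, 0.3)), n = 173L,
    converged = TRUE, stringsAsFactors = FALSE)
  cat <- known_variant_catalog(
    vid = c("rs1", "rs2", "posmatch", "rsgone"),
    chrom = c("1", "1", "2", "9"), pos = c(100L, 200L, 300L, 1L),
    risk_allele = c("G", "C", "T", "A"))
  hits <- replicate_known(res, cat)
  expect_true(hits$flagged[1])          # p = 0.009 < 0.05
  expect_false(hits$flagged[2])         # p = 0.05 exactly: strict <
  # risk allele equal to ref: effect re-signed
  expect_equal(hits$beta[2], 0.5)
  expect_match(hits$orientation[2], "re-signed")
  # chrom+pos fallback; risk allele matches neither -> unknown
  expect_true(hits$found[3])
  expect_identical(hits$orientation[3], "unknown")
  expect_false(hits$found[4])
  expect_identical(hits$reason[4], "not-genotyped")

  # a variant present pre-QC but absent from results reads as filtered
  ds <- make_dataset(matrix(c(0, 1, 2, 1), 4, 1))
  cat2 <- known_variant_catalog("tv001", "1", 1000L, "G")
  hits2 <- replicate_known(res, cat2, dataset = ds)
  expect_identical(hits2$reason, "filtered")
})

test_that("region extraction windows by position on one chromosome", {
  res <- data.frame(
    vid = sprintf("v%d", 1:8),
    chrom = c(rep("1", 5), rep("2", 3)),
    pos = c(1000L, 3000L, 5000L, 7000L, 60000L, 4000L, 5000L, 6000L),
    p = runif(8), stringsAsFactors = FALSE)
  out <- region_extract(res, "v3", flank = 4000)
  expect_identical(out$vid, c("v1", "v2", "v3", "v4"))
  expect_identical(region_extract(res, "v3", flank = 0)$vid, "v3")
  # same chromosome only, even at identical positions
  expect_false(any(region_extract(res, "v7", flank = 2000)$chrom == "1"))
  expect_error(region_extract(res, "nope"), "not present")
})
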