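test_that("the GDP density is symmetric, unimodal, and integrates to 1", {
  set.seed(5)
  b <- rnorm(20, 0, 2)
  expect_equal(gdp_log_density(b, 1, 0.5), gdp_log_density(-b, 1, 0.5))
  for (h in list(c(1, 1), c(0.5, 0.25), c(3, 2))) {
    int <- stats::integrate(function(x) exp(gdp_log_density(x, h[1], h[2])),
                            -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(int, 1, tolerance = 1e-6)
    expect_true(all(gdp_log_density(0, h[1], h[2]) >=
                      gdp_log_density(b, h[1], h[2])))
  }
  expect_error(gdp_log_density(0, -1, 1), "positive")
})

test_that("one M-step on an orthonormal design soft-thresholds exactly", {
  set.seed(11)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))  # orthonormal columns
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 1.5 * X[, 3]))
  w <- c(0.15, 0.15, 0.05, 0.4)
  # one IRLS round from beta = 0: weights are exactly 1/4, so the CD
  # solution of that quadratic is the soft-thresholded least-squares
  # fit to the working response 4*(y - 1/2)
  fit <- polygdp:::.wl1_logistic(X, y, w, numeric(4), 1e-12, 1000L, 1L)
  z <- 4 * crossprod(X, y - 0.5)  # LS coefficients, orthonormal design
  closed <- sign(z) * pmax(abs(z) - 4 * w, 0)
  expect_equal(as.vector(fit$coefficients), as.vector(closed),
               tolerance = 1e-10)
})

test_that("the EM objective is monotone and zeros are exact", {
  d <- rand_logit_data(n = 250, p = 12, seed = 901,
                       beta = c(0.3, 1, -0.8, rep(0, 10)))
  f <- em_map_fit(d$y, d$X, alpha = 1, eta = 0.5)
  expect_true(all(diff(f$objective_trace) >=
                    -1e-6 * (abs(f$objective_trace[-1]) + 1)))
  expect_true(f$converged)
  # exact zeros, consistent df and BIC identity
  expect_true(any(f$coefficients == 0))
  expect_equal(f$df, sum(f$coefficients != 0))
  expect_equal(f$bic, -2 * f$loglik + f$df * log(f$n), tolerance = 1e-10)
})

test_that("vanishing penalty recovers the ML fit", {
  d <- rand_logit_data(n = 200, p = 3, seed = 903)
  ml <- fit_logistic(d$y, d$X)
  f <- em_map_fit(d$y, d$X, alpha = 1, eta = 1e7, standardize = FALSE)
  expect_equal(unname(f$coefficients), unname(ml$coefficients),
               tolerance = 1e-3)
})

test_that("overwhelming penalty zeroes every penalized coefficient", {
  d <- rand_logit_data(n = 200, p = 5, seed = 904)
  f <- em_map_fit(d$y, d$X, alpha = 3, eta = 1e-4)
  expect_true(all(f$coefficients[-1] == 0))
  expect_equal(unname(f$coefficients[1]),
               log(mean(d$y) / (1 - mean(d$y))), tolerance = 1e-4)
})

test_that("EM solution matches brute-force posterior-mode search", {
  set.seed(77)
  n <- 120
  x1 <- rnorm(n); x2 <- 0.5 * x1 + sqrt(0.75) * rnorm(n)
  X <- cbind(1, scale(x1)[, 1], scale(x2)[, 1])
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * X[, 2]))
  pen <- c(FALSE, TRUE, TRUE)
  for (h in list(c(1, 0.5), c(0.5, 0.15))) {
    f <- em_map_fit(y, X, penalize = pen, alpha = h[1], eta = h[2],
                    standardize = FALSE, tol = 1e-12)
    oracle <- brute_force_gdp(y, X, pen, h[1], h[2])
    expect_lt(max(abs(unname(f$coefficients) - oracle)), 1e-3)
  }
})

test_that("BIC selection returns the best fit with sensible tie-breaks", {
  d <- rand_logit_data(n = 150, p = 6, seed = 905,
                       beta = c(0, 1.2, rep(0, 5)))
  single <- bic_select(d$y, d$X, grid = data.frame(alpha = 1, eta = 0.5))
  expect_equal(single$best$alpha, 1)
  expect_equal(single$best$eta, 0.5)
  expect_equal(nrow(single$path), 1)

  sel <- bic_select(d$y, d$X,
                    grid = expand.grid(alpha = c(0.5, 1),
                                       eta = c(0.05, 0.5, 5)))
  expect_equal(sel$best$bic, min(sel$path$bic, na.rm = TRUE))
  expect_error(bic_select(d$y, d$X, grid = data.frame()[0, ]), "empty")
})

test_that("sparsity decreases along the strong-penalty direction", {
  d <- rand_logit_data(n = 300, p = 15, seed = 906,
                       beta = c(0.2, 1, -1, 0.8, rep(0, 12)))
  etas <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 5, 10)
  sel <- bic_select(d$y, d$X, grid = data.frame(alpha = 0.5, eta = etas))
  dfs <- sel$path$df[order(sel$path$eta)]
  expect_true(all(diff(dfs) >= 0))  # plateaus allowed
})

test_that("risk prediction applies the inverse link and stored scaling", {
  mk_model <- function(coefs, centers, scales) {
    structure(list(coefficients = coefs,
                   penalized = c(FALSE, rep(TRUE, length(coefs) - 1)),
                   intercept_col = 1L, centers = centers, scales = scales,
                   covariates = character(0)),
              class = "polygenic_model")
  }
  ds <- make_dataset(matrix(c(0, 1, 2, 1, 0, 2), 3, 2))
  # all-zero model, intercept 0: probability one half everywhere
  m0 <- mk_model(c(`(Intercept)` = 0, tv001 = 0, tv002 = 0),
                 centers = rep(0, 3), scales = rep(1, 3))
  expect_equal(predict_risk(m0, ds), rep(0.5, 3))
  # intercept-only 0.90: logistic(0.90) for every sample
  m1 <- mk_model(c(`(Intercept)` = 0.90, tv001 = 0, tv002 = 0),
                 centers = rep(0, 3), scales = rep(1, 3))
  expect_equal(predict_risk(m1, ds), rep(plogis(0.90), 3),
               tolerance = 1e-12)
  # monotone in a positive-coefficient dosage
  m2 <- mk_model(c(`(Intercept)` = 0, tv001 = 0.8, tv002 = 0),
                 centers = rep(0, 3), scales = rep(1, 3))
  r <- predict_risk(m2, ds)
  expect_true(r[3] > r[2] && r[2] > r[1])  # dosages 2 > 1 > 0
  # missing predictor errors by name
  m3 <- mk_model(c(`(Intercept)` = 0, gone = 0.5),
                 centers = rep(0, 2), scales = rep(1, 2))
  expect_error(predict_risk(m3, ds), "gone")
})

test_that("the model report lists covariates then nonzero SNPs with MAF", {
  cfg <- sim_config(n_case = 90, n_control = 90, m_variants = 40,
                    causal_ids = c(8, 30), causal_betas = c(1.3, -1.2),
                    seed = 83)
  sim <- simulate_cohort(cfg)
  sel <- fit_polygenic(sim$dataset, sim$dataset$variants$vid,
                       grid = data.frame(alpha = 0.5, eta = 0.1))
  tab <- model_report(sel$best, sim$dataset)
  expect_identical(tab$description[1:5],
                   c("Intercept", "Gender", "Age", "BMI", "Smoking"))
  snp_rows <- tab[-(1:5), ]
  nz <- sel$best$coefficients[sim$dataset$variants$vid]
  expect_equal(nrow(snp_rows), sum(nz != 0))
  expect_true(all(snp_rows$estimate != 0))
  for (i in seq_len(nrow(snp_rows))) {
    j <- match(snp_rows$description[i], sim$dataset$variants$vid)
    expect_equal(snp_rows$maf[i],
                 minor_allele_frequency(sim$dataset$dosages[, j]))
  }
  # gene-context annotation from intervals
  ann <- data.frame(chrom = "1", start = 0L, end = 5e6L, gene = "GENE1")
  tab2 <- model_report(sel$best, sim$dataset, annotation = ann)
  expect_true(all(tab2$gene[-(1:5)] == "GENE1"))
})

test_that("degenerate outcomes are rejected", {
  d <- rand_logit_data(n = 50, p = 2, seed = 907)
  expect_error(em_map_fit(rep(1, 50), d$X), "constant")
  expect_error(em_map_fit(d$y, d$X, alpha = 0), "positive")
})
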