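# Fixtures and independent oracles shared across test files.

# Hand-written VCF: 10 records, 2 multiallelic (rs3, rs7); rs2 carries GT
# only (no DS) so the reader must fall back to allele counts.
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    "1\t100\trs1\tA\tG\t.\tPASS\tR2=0.95\tGT:DS\t0/1:0.5\t1/1:1.5",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t300\trs3\tG\tA,T\t.\tPASS\tR2=0.9\tGT:DS\t0/1:1.0\t0/0:0.0",
    "1\t400\trs4\tT\tC\t.\tPASS\tR2=0.80\tGT:DS\t0/0:0.1\t0/1:0.9",
    "1\t500\trs5\tA\tC\t.\tPASS\tR2=0.29\tGT:DS\t0/1:1.0\t0/1:1.0",
    "2\t100\trs6\tG\tT\t.\tPASS\tR2=0.3\tGT:DS\t1/1:2.0\t0/0:0.0",
    "2\t200\trs7\tC\tA,G\t.\tPASS\t.\tGT:DS\t0/1:1.0\t0/1:1.0",
    "2\t300\trs8\tA\tT\t.\tPASS\t.\tGT:DS\t0/1:1.2\t0/0:0.2",
    "2\t400\trs9\tT\tG\t.\tPASS\tR2=0.99\tGT:DS\t./.:.\t0/1:1.0",
    "2\t500\trs10\tC\tG\t.\tPASS\tR2=0.5\tGT:DS\t0/1:0.7\t1/1:1.8")
  writeLines(lines, path)
  path
}

write_fixture_covariates <- function(path, n = 6) {
  hdr <- "sid,status,sex,age,bmi,smoking,eas,sas,eur,afr"
  rows <- sprintf("P%d,%s,%s,%d,%.1f,%s,0.92,0.07,0.01,0.00",
                  seq_len(n),
                  rep(c("case", "control"), length.out = n),
                  rep(c("male", "female"), length.out = n),
                  45 + seq_len(n), 20 + seq_len(n) / 2,
                  rep(c("smoker", "non-smoker"), length.out = n))
  writeLines(c(hdr, rows), path)
  path
}

# small deterministic dataset built directly from matrices
make_dataset <- function(dosages, status = NULL, impq = NA_real_,
                         pos_step = 2000L) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(status))
    status <- rep(c("case", "control"), length.out = n)
  set.seed(42)
  samples <- sample_table(
    sid = sprintf("T%03d", seq_len(n)), status = status,
    sex = rep(c("male", "female"), length.out = n),
    age = seq(30, 70, length.out = n),
    bmi = seq(19, 30, length.out = n),
    smoking = rep(c("smoker", "non-smoker", "non-smoker"),
                  length.out = n),
    eas = 0.9, sas = 0.06, eur = 0.03, afr = 0.01)
  variants <- variant_table(
    chrom = rep("1", m), pos = 1000L + (seq_len(m) - 1L) * pos_step,
    vid = sprintf("tv%03d", seq_len(m)),
    ref = rep("A", m), alt = rep("G", m), impq = rep(impq, length.out = m))
  dosage_dataset(samples, variants, dosages)
}

# random logistic-regression data for oracle comparisons
rand_logit_data <- function(n, p, seed, beta = NULL) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  if (is.null(beta)) beta <- c(0.2, rnorm(p, 0, 0.5))
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(y = y, X = X, beta = beta)
}

# exact posterior-mode objective for the GDP MAP problem
gdp_objective <- function(beta, y, X, penalize, alpha, eta) {
  eta_lin <- as.vector(X %*% beta)
  ll <- sum(y * eta_lin -
              ifelse(eta_lin > 35, eta_lin, log1p(exp(eta_lin))))
  ll + sum(gdp_log_density(beta[penalize], alpha, eta))
}

# brute-force grid-refinement maximizer of the exact GDP posterior mode,
# independent of the EM path (3 coordinates)
brute_force_gdp <- function(y, X, penalize, alpha, eta,
                            width = 3, levels = 8, pts = 13) {
  center <- numeric(ncol(X))
  step <- 2 * width / (pts - 1)
  for (lev in seq_len(levels)) {
    grids <- lapply(center, function(c0)
      seq(c0 - step * (pts - 1) / 2, c0 + step * (pts - 1) / 2,
          length.out = pts))
    B <- as.matrix(expand.grid(grids))
    eta_lin <- X %*% t(B)
    ll <- colSums(y * eta_lin -
                    ifelse(eta_lin > 35, eta_lin, log1p(exp(eta_lin))))
    prior <- rowSums(matrix(
      gdp_log_density(as.vector(B[, penalize, drop = FALSE]),
                      alpha, eta),
      nrow = nrow(B)))
    center <- as.numeric(B[which.max(ll + prior), ])
    step <- step / 3
  }
  center
}

# quadrature oracle for the Wakefield approximate Bayes factor
quadrature_log10_bf <- function(beta_hat, se, W) {
  marg <- stats::integrate(function(b)
    stats::dnorm(beta_hat, b, se) * stats::dnorm(b, 0, sqrt(W)),
    -Inf, Inf, rel.tol = 1e-12)$value
  log10(marg / stats::dnorm(beta_hat, 0, se))
}
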