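#' Wakefield approximate Bayes factor
#'
#' Single-variant approximate Bayes factor of the alternative (nonzero
#' effect, normal prior with variance `prior_w` on the log-odds scale)
#' against the null, computed from the Wald estimate and its standard
#' error: with `V = se^2` and `z = beta_hat/se`,
#' `BF10 = sqrt(V/(V+W)) * exp(z^2 * W / (2*(V+W)))`.
#'
#' @param beta_hat effect estimate (log-odds).
#' @param se its standard error (> 0).
#' @param prior_w prior effect variance W (>= 0); the default 0.25
#'   corresponds to a prior SD of 0.5 on the log-odds scale.
#' @return `log10(BF10)`; vectorized over `beta_hat`/`se`.
#' @export
wakefield_bf <- function(beta_hat, se, prior_w = 0.25) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (any(prior_w < 0)) stop("prior_w must be >= 0", call. = FALSE)
  V <- se^2
  z <- beta_hat / se
  (0.5 * log(V / (V + prior_w)) +
      z^2 * prior_w / (2 * (V + prior_w))) / log(10)
}

#' Screen variants by approximate Bayes factors
#'
#' Ranks every variant by the Bayes factor of its covariate-adjusted
#' marginal model against the covariate-only null and selects the top `K`
#' as candidate predictors for the joint polygenic model.  The screening
#' covariates are sex, age, BMI and smoking only (no ancestry terms).
#' Two approximations are available: Wakefield's ABF from the Wald
#' estimate (default), or the BIC-based approximation
#' `BF10 = exp((BIC_null - BIC_alt)/2)`.
#'
#' @param dataset a QC-filtered [dosage_dataset()].
#' @param K number of variants to select (default 200, keeping the
#'   candidate count close to typical sample size); when `K >= m` all are
#'   selected.
#' @param prior_w Wakefield prior effect variance (default 0.25).
#' @param mode `"wakefield"` or `"bic"`.
#' @param covariates adjustment covariates (default
#'   `sex, age, bmi, smoking`).
#' @return A data.frame (schema `screen` plus `p`): `vid, log10_bf, p,
#'   rank, selected`, in dataset (genomic) order.  Ranks are descending in
#'   `log10_bf` with ties broken by ascending p then genomic position;
#'   non-converged variants have `NA` Bayes factors and rank last.
#' @export
screen_variants <- function(dataset, K = 200, prior_w = 0.25,
                            mode = c("wakefield", "bic"),
                            covariates = c("sex", "age", "bmi",
                                           "smoking")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "dosage_dataset"), K >= 1)
  y <- as.numeric(dataset$samples$status == "case")
  C <- build_covariate_matrix(dataset$samples, covariates)
  n <- nrow(C)
  dos <- mean_impute_dosages(dataset$dosages)
  m <- ncol(dos)
  X <- cbind(C[, 1, drop = FALSE], dosage = 0, C[, -1, drop = FALSE])

  null_ll <- if (mode == "bic") .irls_logistic(C, y)$loglik else NA_real_

  log10_bf <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    d <- dos[, j]
    if (diff(range(d)) == 0) next
    X[, 2] <- d
    fit <- .irls_logistic(X, y, 1e-8, 1e-10, 100L)
    if (!fit$converged) next
    b <- fit$coefficients[2]
    s <- sqrt(fit$vcov[2, 2])
    p[j] <- 2 * pnorm(-abs(b / s))
    log10_bf[j] <- if (mode == "wakefield") {
      wakefield_bf(b, s, prior_w)
    } else {
      bic_alt <- -2 * fit$loglik + ncol(X) * log(n)
      bic_null <- -2 * null_ll + ncol(C) * log(n)
      (bic_null - bic_alt) / 2 / log(10)
    }
  }
  v <- dataset$variants
  ord <- order(-ifelse(is.na(log10_bf), -Inf, log10_bf),
               ifelse(is.na(p), Inf, p), v$chrom, v$pos)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  out <- data.frame(vid = v$vid, chrom = v$chrom, pos = v$pos,
                    log10_bf = log10_bf, p = p, rank = rank,
                    selected = rank <= K, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
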