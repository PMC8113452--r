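---
title: "Methods: case-control GWAS scanning and sparse polygenic modelling with a generalized double Pareto prior"
author: "polygdp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GWAS scanning and sparse GDP polygenic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope and model overview

`polygdp` implements the statistical pipeline of a small case-control
genome-wide association study on imputed genotype dosages, of the kind run
in admixed populations where sample sizes are modest and the scientific
yield comes from (a) replicating previously reported risk variants and
(b) building a sparse multi-variant risk model rather than from
genome-wide discovery. The stages are:

1. **Variant QC** — drop imputed variants with imputation quality
   below 0.3 and variants with minor allele frequency below 1%
   (both thresholds strict, so boundary values are retained).
2. **Marginal scan** — per-variant maximum-likelihood logistic
   regression of case status on the alternate-allele dosage, adjusted for
   sex, age, BMI, smoking, and ancestry proportions; Wald tests; flagging
   at the historical genome-wide level 5e-8; replication lookup of a
   known-variant catalog at p < 0.05.
3. **Bayes-factor screen** — rank variants by an approximate Bayes
   factor of the covariate-adjusted marginal model against the
   covariate-only null and keep the top K = 200, keeping the joint-model
   candidate count close to the sample size.
4. **Sparse polygenic model** — MAP logistic regression over the
   covariates plus the screened SNPs under independent generalized double
   Pareto (GDP) priors, fit by EM so that many coefficients are
   *identically zero*; the prior's hyperparameters are chosen by BIC.
5. **Cohort statistics** — Welch t and chi-square comparisons of the
   case and control covariate distributions, from raw data or from
   printed group summaries.

# The marginal scan

Each variant is tested in the model

$$\operatorname{logit} P(Y_i = 1) = \beta_0 + \beta_d d_{ij} + \gamma' c_i$$

where $d_{ij}$ is the dosage in $[0,2]$ (missing values mean-imputed per
variant) and $c_i$ the covariates. The fitter is a Newton–Raphson/IRLS
maximum-likelihood routine (C++ kernel) with convergence declared when the
largest score component falls below $10^{-8}$ or the relative
log-likelihood change falls below $10^{-10}$, and with quasi-separation
(coefficients diverging past 15 on the log-odds scale with a
non-vanishing score) flagged as non-convergence rather than silently
reported. Wald p-values use the inverse observed information. The test
suite cross-checks coefficients, standard errors and p-values against the
reference GLM implementation in base R to $10^{-6}$ relative accuracy,
and against the closed-form 2×2 log odds ratio in the binary,
covariate-free case.

Continuous covariates are standardized inside the scan. This leaves the
dosage effect and its Wald statistic unchanged (the test suite asserts
invariance of $|z|$ under affine covariate rescaling) and only improves
conditioning. The dominant ancestry component (EAS) is dropped from the
covariate set to avoid the sum-to-one collinearity, so the adjustment
uses SAS, EUR and AFR.

# The screen

Wakefield's approximate Bayes factor is computed from the Wald summary
$(\hat\beta, \mathrm{se})$: with $V = \mathrm{se}^2$, $z = \hat\beta /
\mathrm{se}$ and prior effect variance $W$,

$$\mathrm{BF}_{10} = \sqrt{\frac{V}{V+W}}
  \exp\!\left(\frac{z^2 W}{2(V+W)}\right).$$

The default prior SD is 0.5 on the log-odds scale ($W = 0.25$), a
conventional weakly-informative choice for common-variant effects. A
BIC-based approximation $\mathrm{BF}_{10} = \exp((\mathrm{BIC}_0 -
\mathrm{BIC}_1)/2)$ is available as an alternative mode; both are
monotone in $|z|$ at fixed se, and which a given study used is rarely
recoverable from a report, so the mode is exposed in configuration.
The screening adjustment set is sex, age, BMI and smoking (no ancestry
terms), matching the covariates later used in the joint model. Ties in
the Bayes factor are broken by ascending p-value and then genomic
position, so ranks are deterministic.

# The sparse GDP polygenic model

The joint model places an independent GDP prior on every penalized
coefficient (the four covariates and all candidate SNPs; the intercept is
unpenalized):

$$f(\beta \mid \alpha, \eta) = \frac{\alpha}{2\eta}
  \left(1 + \frac{|\beta|}{\eta}\right)^{-(\alpha+1)},
  \qquad \alpha, \eta > 0.$$

This density is a Laplace distribution whose scale is mixed over a Gamma;
heavy Pareto tails mean large effects are barely shrunk while the spike
of mass at zero drives small effects exactly to zero at the posterior
mode. The MAP estimate is computed by EM over the latent Laplace scales:

* **E-step.** Given the current $\beta$, each penalized coefficient
  receives the weight $w_j = (\alpha + 1) / (|\beta_j| + \eta)$.
* **M-step.** Maximize $\ell(\beta) - \sum_j w_j |\beta_j|$ — a
  weighted-L1 logistic problem — by cyclic coordinate descent with
  soft-threshold updates. Quadratic approximations use current IRLS
  weights (fast, Newton-like); any round that fails to lower the exact
  penalized objective is discarded and replaced by descent cycles under
  the global 1/4 logistic curvature bound, which cannot increase the
  objective. Coordinate convergence tolerance is $10^{-10}$ in
  curvature-scaled units.
* **Outer loop.** Until the relative change of the penalized
  log-posterior falls below $10^{-8}$ (at most 500 iterations). The
  log-posterior is verified to be non-decreasing at every iteration and
  the fit aborts loudly if it is not.

All non-intercept predictors are standardized before fitting and
coefficients are reported on the standardized scale, with the scaling
constants stored in the model object and applied at prediction time.
Coefficients below $10^{-8}$ in magnitude are reported as exact zeros;
`df` counts nonzero coefficients including the intercept, and
$\mathrm{BIC} = -2\hat\ell + \mathrm{df}\log n$.

## Hyperparameter grid

BIC selection runs over $\alpha \in \{0.1, 0.5, 1, 2, 3\}$ and $\eta \in
\{0.05, 0.1, 0.25, 0.5, 1, 2, 5, 10\}$, warm-starting each fit from the
previous solution along the ascending-$\eta$ (strong-to-weak) direction
within each $\alpha$, as regularization-path solvers conventionally do.
The $\eta$ range was chosen so the path truly spans its extremes: at the
weak end the fit approaches the unpenalized ML solution (the test suite
checks agreement to $10^{-3}$), and at the strong end the weight at zero,
$(\alpha+1)/\eta$, exceeds any plausible score so every penalized
coefficient is zeroed and the null model is always on the path — without
that, BIC could never select a fully sparse model no matter how weak the
evidence. Ties in BIC break toward smaller `df`, then larger $\eta$.

## What the EM can and cannot promise

The penalized objective is non-convex (the GDP log-prior is concave in
$|\beta|$), so the EM converges to a local mode that can depend on the
starting point; warm-starting along the path makes the reported path
deterministic and reproducible but is still a heuristic. On
two-predictor problems the test suite compares the EM solution against a
brute-force grid-refinement search of the exact posterior-mode objective
and requires agreement to $10^{-3}$ per coordinate.

# Cohort statistics

Group comparisons default to the tests that reproduce conventionally
printed cohort tables: Welch's unequal-variance t with Satterthwaite
degrees of freedom for continuous rows, and the Yates-corrected
chi-square for 2×2 categorical rows. The Yates correction matters in
practice: on a near-balanced sex table (38/51 vs 36/48) the corrected
test returns p > 0.99 whereas the uncorrected one gives about 0.98, and
published tables that print "> 0.99" are only reproduced with the
correction. For r×c tables the Pearson chi-square is reported, with an
additional Monte-Carlo p-value (fixed-margin permutation) whenever an
expected count falls below 5. Ancestry-proportion rows are compared
descriptively by Welch t on the per-sample proportions.

# The synthetic-data generator

Every downstream stage is exercised on generated data with known truth,
since case-control genotype data of this kind are rarely depositable.
The generator emulates:

* **Genotypes.** A Gaussian-copula threshold model: per haplotype, a
  latent standard-normal AR(1) vector with correlation $\rho^{|i-j|}$
  within blocks of `block_size` variants (independent across blocks),
  thresholded at the normal quantile of the variant's allele frequency;
  dosage = sum of two independent haplotypes. This yields
  Hardy–Weinberg-consistent integer dosages with block LD whose strength
  grows with $\rho$ (asserted over a $\rho$ grid in the tests). Defaults:
  1000 variants, blocks of 10, $\rho = 0.5$, allele frequencies uniform
  on (0.05, 0.45), simulated imputation quality uniform on (0.7, 1).
* **Covariates.** Sex male with probability 0.57; age normal(52, 14)
  truncated at 18 years; BMI normal(23, 3.5) truncated at 10 kg/m²;
  smoking Bernoulli(0.25); ancestry Dirichlet with concentration
  (18.4, 1.4, 0.2, 0.02) × 5, giving EAS-dominant proportions around
  0.92. These match the cohort structure of a South-East-Asian
  case-control study of 84 cases and 89 controls, which is the default
  target size.
* **Disease.** A logistic model on the standardized continuous
  covariates, the binary covariates, and the causal dosages. Default
  covariate effects (log-odds): sex 0, age +0.25 per SD, BMI −0.9 per
  SD, smoking +1.3 — the directions and approximate magnitudes implied
  by a cohort whose cases smoke more and, being late-stage patients,
  weigh less. Default intercept −2.5. Sampling is retrospective: the
  population is drawn until both the case and the control quota are met,
  so the realized study intercept is design-driven while slopes remain
  estimable; a draw budget (default 400 × target size) turns a hopeless
  accrual into an informative error.

The generator does **not** emulate realistic recombination maps,
population stratification linked to genotype, genotyping batch effects,
Hardy–Weinberg violations, or non-logistic disease mechanisms. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness of the pipeline to the full messiness
of real array data.

# Numerical and design choices

* Dosage FORMAT tag `DS` and INFO quality tag `R2` by default
  (imputation-server dialect), both configurable; multiallelic VCF
  records are skipped with a warning because the analysis is defined on
  biallelic dosages.
* Missing dosages are mean-imputed per variant at analysis time; the
  handling of post-imputation missingness is a package choice, made
  because it is standard GWAS practice and keeps design matrices
  complete.
* MAF is computed on the pooled analysis sample (cases plus controls).
* QC thresholds are strict inequalities exactly as conventionally
  printed; a variant failing both filters is attributed to the
  imputation-quality filter, which runs first.
* Separation in the scan is flagged-and-excluded rather than handled by
  penalized fits, keeping the scan purely ML.
* In the joint model the ancestry proportions are excluded by default
  (configurable), matching the covariate set of the screening step.
* Simulation problem sizes used by the test-suite properties: null
  calibration pools 50 cohorts of n = 400 with 500 variants; screening
  sensitivity uses 100 cohorts of n = 400 with 1000 variants;
  sparsity/recovery uses 50 cohorts of n = 400 with 200 candidates
  (5 causal, |β| in 0.6–1.0). These sizes make Monte-Carlo bands tight
  enough to be informative while keeping the default suite comfortably
  runnable on a laptop.

# Known limitations

* Wald inference degrades for very rare variants at small n; the 1% MAF
  filter removes the worst cases but se-based Bayes factors inherit the
  remaining small-sample bias (the marginal OR of a planted effect at
  n ≈ 173 overshoots slightly on average, as expected of ML logistic
  estimates at that size).
* BIC model selection retains a predictor whenever its (shrunk)
  deviance improvement exceeds $\log n$; among hundreds of null
  candidates the maximum Wald statistic frequently crosses that bar, so
  on pure noise the selected model carries a small number of false
  positives in a substantial fraction of datasets. This is a property of
  BIC itself, not of the EM: the package's calibration tests quantify it
  rather than hide it.
* No X-chromosome dosage handling, genomic-control correction, or
  mixed-model association; candidate sets beyond a few hundred variants
  are better screened before the joint fit, as the pipeline does.
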