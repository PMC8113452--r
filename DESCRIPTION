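Package: polygdp
Title: Case-Control GWAS Scanning and Sparse Polygenic Risk Modelling
    with a Generalized Double Pareto Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end statistical pipeline for small case-control
    genome-wide association studies on imputed genotype dosages:
    variant-level quality control (imputation-quality and minor-allele
    frequency filters), covariate-adjusted marginal logistic regression
    scans with genome-wide flagging and known-variant replication lookup,
    approximate Bayes-factor screening of candidate variants, and a
    sparse polygenic risk model fit by maximum a posteriori
    expectation-maximization under a generalized double Pareto shrinkage
    prior with hyperparameters selected by the Bayesian information
    criterion.  Includes a synthetic-data generator with block-structured
    linkage disequilibrium and known ground truth, and two-sample cohort
    comparison utilities operating on raw data or printed summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
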