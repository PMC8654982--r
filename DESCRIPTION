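Package: revscreen
Title: Transcriptome-Reversal Drug-Repurposing Screens with Multi-Level
    Meta-Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectivity-map style drug-repurposing screens that
    match compound perturbation signatures against multi-region disease
    differential-expression profiles. Signatures are scored by Pearson
    correlation with an analytic sampling variance, pooled per compound with
    a multi-level random-effects meta-regression (restricted maximum
    likelihood with nested variance components), and classified as reversal
    candidates under Benjamini-Hochberg false-discovery-rate control.
    Includes re-scoring against independent follow-up datasets with a
    prioritization rule, statistics for a behavioral validation assay
    (calibration curves, type-III factorial ANOVA, pooled-variance post-hoc
    t tests, Fisher's exact tests), and a synthetic-data generator that
    emulates the statistical structure of post-mortem brain
    differential-expression tables, L1000-like signature libraries, and fly
    behavioral records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    igraph,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
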