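Package: mircascade
Title: Circulating miRNA Biomarker Screening and Neural Network Cascade
    Modeling for Two-Class Expression Cohorts
Version: 0.1.0
Authors@R:
    person("mircascade", "developers", email = "mircascade@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering small diagnostic biomarker
    panels from feature-by-sample expression matrices with binary disease
    labels, modeled on large circulating-miRNA microarray cohorts.  Stages:
    per-feature ROC/AUC screening with Mann-Whitney significance, Spearman
    collinearity-network construction and AUC-ranked pruning, greedy
    construction of a cascade of small radial-basis-function network units
    (n-11-1), a stepwise multiple-linear-regression baseline, tenfold
    cross-validation and independent-set evaluation, plus a seeded Gaussian
    copula cohort simulator with closed-form AUC calibration so the whole
    pipeline is testable without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
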