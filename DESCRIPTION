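Package: clinedrift
Title: Ancestry Clines and Drift-Aware Outlier Scans for Replicated Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide and local ancestry across
    admixture hybrid zones sampled along geographic transects. Implements
    logistic cline fitting by multi-start nonlinear least squares with AIC
    predictor comparison, an empirical population ancestry
    variance-covariance (K) matrix with three neutral simulators
    (Poisson-binomial, variance-only and full multivariate-normal drift
    models), simulation-calibrated false-discovery-rate outlier scans with
    region merging and gene overlap, per-SNP cline steepness scans with
    recombination-rate quintile enrichment via cM block bootstrap,
    nucleotide diversity and Hudson's F_ST estimators with block-bootstrap
    confidence intervals, ancestry-informative marker discovery, wing-length
    ancestry regressions and admixture mapping with an analytic genome-wide
    significance threshold. Includes a seeded synthetic-data generator that
    emulates a two-continent hybrid-zone study design with known truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
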