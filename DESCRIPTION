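Package: psychoscreen
Title: Screening Longitudinal Multi-Omics Data for Mood-Associated Gut
    Microbes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying candidate
    psychobiotics - gut microbes whose abundance tracks host mood - from
    longitudinal multi-omics cohorts paired with repeated mood
    questionnaires (POMS and SCL-90 panels). Implements log2/quotient
    normalization and prevalence filtering, autocorrelation-based
    stationarity gating of time series (Ljung-Box portmanteau test), PCA
    ordination with MANOVA on scores and Mahalanobis group distances,
    NIPALS partial least squares (PLS1) regression with leave-one-out
    Q2/RMSECV cross-validation and variable-importance-in-projection
    (VIP) scores, and the two-stage VIP-majority-vote plus
    sign-consistent Spearman screen that yields candidate taxa, key
    functional features, and linked metabolites. Ships a synthetic cohort
    generator with planted signal taxa for power and false-positive
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
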