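Package: thermopred
Title: Personality and Predictability in Thermoregulatory and Classic
    Behavioural Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies animal personality (behavioural type) and behavioural
    predictability in repeated-measures behavioural data, with an emphasis on
    ectotherm thermoregulatory traits (selected body temperature, set-point
    range width, voluntary thermal maximum) alongside classic behavioural
    traits (movement activity, sheltering, risk-taking).  Provides a
    synthetic-data generator for the underlying repeated-assay design, trait
    derivation from raw observation logs, Bayesian double-hierarchical
    (location-scale) Gaussian mixed models with correlated individual random
    effects fitted by an adaptive MCMC sampler, repeatability and
    coefficient-of-predictability statistics, and a multivariate mixed model
    that decomposes phenotypic correlations into between- and
    within-individual components for behavioural-syndrome detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    dplyr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
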