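Package: morphmod
Title: Modularity and Morphological Integration of Multi-Trait Body Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing variational modularity
    and morphological integration in tables of linear body measurements across
    sex/age/habitat groups. Provides allometric size correction (power-law
    normalisation to a common theoretical body size), population-structure
    adjustment, per-group Pearson correlation and covariance matrices with
    bootstrap repeatability and Mantel permutation tests, a priori modularity
    hypotheses encoded as binary connectivity matrices with likelihood-based
    model comparison (Fisher-z correlation likelihoods, AICc, Akaike weights),
    conditional-independence graphs from full partial correlations with the
    edge-exclusion deviance test, the standardized eigenvalue-variance index of
    integration with bootstrap group comparisons, random-skewers evolvability,
    conditional evolvability and constraints indices, and principal coordinate
    ordination of among-group covariance-matrix distances. A seeded synthetic
    trait-table generator with allometric size structure and block-modular
    residual correlations makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
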