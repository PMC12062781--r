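Package: nichetrait
Title: Climatic Niche Position and Body-Size Trends with Phylogenetic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking vertebrate body-size records to species'
    positions within their realized thermal and aridity niches. Derives
    per-species monthly niche limits from range geometry and gridded monthly
    climate over a fixed baseline, computes thermal and aridity position
    indices (TPI/API) for individual observations, applies robust
    median-absolute-deviation record cleaning, attaches land-use and realm
    covariates, and fits Gaussian phylogenetic mixed models with dual
    (independent and phylogenetically correlated) random slopes via a sparse
    profiled restricted-likelihood optimizer. Includes a seeded synthetic-world
    generator with known ground truth, a model-validation battery (VIF, spline
    correlograms, Durbin-Watson resampling, influence screening, posterior
    predictive checks), and a reproducible pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    minqa,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
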