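Package: scalesdm
Title: Multi-Scale Presence-Background Species Distribution Models with
    Sampling-Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-scale presence-background habitat
    modelling. Derives scale-optimized predictors from raster layers with a
    circular focal-statistics engine (terrain indices, moving-window
    landscape-pattern metrics), fits L1-regularized maximum-entropy models
    with linear and quadratic features, performs univariate scale-of-effect
    optimization, collinearity filtering and category-constrained model
    selection, corrects occurrence sampling bias by spatial rarefaction and
    Gaussian-kernel background weighting, and scores ensembles against
    simulated reference models with Schoener's D niche overlap. Includes a
    synthetic-landscape and virtual-species generator so the full pipeline is
    testable without external GIS data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
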