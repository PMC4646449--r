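Package: scenhab
Title: Scenario-Led Landscape Simulation and Habitat Suitability Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the impact of declarative land-use-change
    scenarios on habitat suitability for species of conservation concern.
    Simulates scenarios on categorical raster landscapes by stochastic patch
    growth from random starting locations, fits a presence-background
    maximum-entropy (maxent) suitability model with L1 regularisation and
    AICc-based selection of the regularisation multiplier, projects the model
    onto each simulated landscape, and compares suitable-area proportions
    across scenario ensembles and matched null scenarios with nonparametric
    tests. Includes focal-window class-proportion predictors, unsupervised
    image classification (PCA plus k-means), patch-level landscape metrics,
    and a synthetic-landscape generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
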