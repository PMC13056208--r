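Package: metoselect
Title: Hybrid Exponential-Trigonometric Optimization for Wrapper Feature
    Selection on Functional Connectivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the METO hybrid metaheuristic -- Exponential-
    Trigonometric Optimization (ETO) control flow with fitness-proportional
    injection of Arithmetic Optimization Algorithm (AOA) operators and a
    periodic Guided Learning Strategy (GLS) -- as a reusable continuous
    optimizer and as a binary wrapper feature selector driven by a
    K-nearest-neighbour error fitness. Also provides the resting-state fMRI
    feature-extraction stage used in autism-spectrum-disorder detection
    studies (Pearson functional connectivity, upper-triangle vectorization,
    Fisher-score filtering, stacked sparse denoising autoencoder pre-training
    with MLP fine-tuning), classification metrics with rank-based AUC, and
    seeded synthetic-data generators so the full workflow is exercisable
    without any imaging download.
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
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
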