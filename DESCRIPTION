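Package: connectoms
Title: Structural Connectome Thresholding, Global Graph Metrics, and
    Clinical-Course Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for weighted structural brain connectomes:
    proportional thresholding of streamline-count connectivity matrices,
    six global graph metrics (density, assortativity, transitivity, global
    efficiency, modularity, characteristic path length), a coefficient-of-
    variation procedure for selecting the binarization threshold,
    nonparametric group comparison, and RBF-kernel support vector machine
    classification of subject groups with grid-searched hyperparameters and
    stratified cross-validation. Includes a synthetic cohort generator that
    plants group-specific network structure on latent streamline
    intensities so the full pipeline can be exercised and validated without
    imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
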