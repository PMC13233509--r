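Package: uavppc
Title: Plant Phosphorus Estimation from UAV RGB and Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating winter wheat plant phosphorus content (PPC)
    from paired UAV RGB and six-band multispectral imagery. Provides a seeded
    synthetic scene generator emulating a five-rate phosphorus field trial,
    plot-ROI raster extraction with inward buffering, the standard colour and
    vegetation indices, dimidiate-pixel fractional vegetation cover,
    moving-window GLCM texture features with normalized-difference, ratio and
    difference texture indices, three feature-selection schemes (Pearson
    screening, random-forest importance ranking, RReliefF weighting), and
    random-forest, support-vector and k-nearest-neighbour regression of PPC
    with R2, RMSE and RPD evaluation plus per-pixel inversion maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    withr,
    mgcv,
    randomForest,
    e1071,
    caret,
    generics,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
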