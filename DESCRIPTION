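Package: cellheading
Title: Predicting the Future Direction of Cell Migration from Single Image Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the future direction of cell movement from a
    single phase-contrast image patch. Implements trajectory annotation of
    four-quadrant moving directions at a net-displacement threshold, patch
    extraction and normalization, a 14-layer convolutional neural network
    trained with class-weighted stochastic gradient descent under 4-fold
    cross-validation, and three attribution methods (guided backpropagation,
    deep Taylor decomposition, and occlusion maps) for visualizing the
    morphological features - protrusions, trailing edge, halo - that drive
    the prediction. Includes a seeded generator of synthetic migrating-cell
    movies with ground-truth tracks in which cell morphology encodes the
    future heading, so the full pipeline can be exercised end to end without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
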