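Package: hdcnet
Title: Hierarchical Dilation Convolutional Networks for Retinal Vessel
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, trains and evaluates U-shaped convolutional networks for
    pixel-level retinal vessel segmentation, including hierarchical dilation
    convolution blocks, spatial attention, residual dual efficient channel
    attention on the skip connections, and structured DropBlock
    regularization.  Ships the full data pipeline (padding, restoration,
    corner cropping, the four standard augmentations), pixel-level evaluation
    metrics (sensitivity, specificity, accuracy, F1, rank-based AUC), a
    seeded synthetic fundus phantom generator so everything runs without a
    dataset download, and a training protocol with Adam and binary
    cross-entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
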