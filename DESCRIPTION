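Package: ridgeseg
Title: Farmland Ridge Segmentation with Strip Pooling and Atrous Spatial
    Pyramid Pooling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semantic segmentation of farmland ridges in low-altitude aerial
    imagery using an encoder-decoder convolutional network with strip
    pooling in every decoder stage and an atrous-spatial-pyramid-pooling
    bottleneck. Implements the full network (forward and backward passes in
    compiled code), pixel-wise cross-entropy training with SGD, confusion
    based evaluation metrics (accuracy, precision, recall, IoU, mIoU),
    tiled inference for arbitrarily large rasters, a synthetic ridge-scene
    generator for reproducible experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
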