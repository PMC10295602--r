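Package: vesselseg
Title: Residual U-Net with Full-Scale Skip Connections for Retinal
    Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation of retinal blood vessels in fundus and
    OCT-angiography images with an improved U-Net: residual convolution
    blocks in encoder and decoder, an inception (multi-kernel) bottleneck,
    and full-scale skip connections that fuse every encoder scale and the
    decoder chain into each decoder stage. Includes the accompanying
    preprocessing chain (grayscale conversion, bilateral filtering, CLAHE,
    gamma correction), paired image/mask geometric augmentation,
    pixel-level evaluation statistics (accuracy, precision, recall, F1,
    IoU), a seeded synthetic vascular-tree image generator for
    self-contained experiments, and a small command-line interface. The
    network layers, reverse-mode gradients and the Adam optimizer are
    implemented in the package with C++ kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'synthetic.R'
    'augment.R'
    'io.R'
    'metrics.R'
    'tape.R'
    'model.R'
    'train.R'
    'preprocess.R'
    'pipeline.R'
    'cli.R'
    'vesselseg-package.R'
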