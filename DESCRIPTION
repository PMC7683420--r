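Package: wavesel
Title: Embedded Wavelength Selection and Classification for NIR Hyperspectral Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for near-infrared (NIR) hyperspectral analysis of crop
    kernels: reflectance calibration, kernel segmentation and per-kernel mean
    spectra extraction; an embedded convolutional feature selector (CNN-FS)
    built on a trainable per-channel selection layer with a ReLU score vector
    and a sparsity-penalized classification loss; an attention-gated 1-D
    convolutional classifier (CNN-ATT); conventional selector baselines
    (chi-square univariate scores, extremely randomized trees, sparse linear
    SVM) and classifier baselines (PLS discriminant analysis with component
    search, RBF support vector classification with grid search); and a
    synthetic-spectra benchmark generator with planted informative channels
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    igraph,
    ranger,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
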