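Package: dscint
Title: Attention-Augmented CNN Classification of Whole-Body Bone Scintigrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass classification of whole-body planar bone scintigraphy
    (normal, bone metastasis, arthritis, thyroid carcinoma) with an
    eight-weight-layer convolutional neural network carrying a cascaded
    channel/spatial attention module. Includes minimal DICOM input/output for
    16-bit planar uptake matrices, parametric data augmentation (mirroring,
    translation, rotation) with class rebalancing, a synthetic scintigram
    phantom generator with Poisson counting noise for desk-scale validation,
    patient-grouped train/test splitting, and multiclass evaluation metrics
    (one-vs-rest accuracy, precision, recall, specificity, F-1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
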