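Package: latentcadx
Title: Weakly-Supervised Joint Classification and Segmentation of
    Lesions from Circumscribing Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns precise lesion boundaries from coarse, circumscribing
    hand-drawn annotations on grayscale tissue patches. Implements a joint
    classification-segmentation convolutional model with a residual encoder,
    region-proposal pretraining head and skip-connected deconvolution
    decoder, trained under a weighted objective that penalizes in-bounds and
    out-of-bounds segmentation errors separately. Ships the matching
    evaluation suite (intersection-over-prediction, intersection-over-
    annotation, confused pixels, average precision at fixed IOU thresholds),
    an optical-density calibration pipeline for raw scans, and a seedable
    synthetic phantom generator so the whole method is testable on a desktop
    CPU without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
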