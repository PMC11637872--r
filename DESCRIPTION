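Package: microdetect
Title: Single-Stage Object Detection for Herbal Powder Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for detecting diagnostic feature cells in
    microscopy images of powdered medicinal herbs. Provides a deterministic
    synthetic slide generator emulating the statistical structure of annotated
    powder micrograph collections (strong class imbalance, small, edge-truncated
    and blurred cells), a split-recombine data augmentation with exact bounding
    box remapping and class balancing, squeeze-excitation and efficient channel
    attention operators, a compact three-scale anchor-based detector trained
    with a squared-error grid loss and IoU-valued confidence targets, decoding
    and non-maximum suppression, a full detection evaluation suite (per-class
    precision/recall/AP, mAP at IoU 0.5 and 0.5:0.95, Matthews correlation,
    ROC/AUC), and a five-fold cross-validation pipeline with box-cluster
    majority voting over the fold models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
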