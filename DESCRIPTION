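Package: mitostage
Title: Recurrent Cell-Cycle Stage Classification for Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-frame classification of cell-cycle stages (interphase, mitotic
    phases, post-mitosis) in single-cell 2D+t fluorescence microscopy crops.
    Implements a time-encoded residual network in which convolutional gated
    recurrent units propagate features between frames at three spatial scales,
    an auxiliary center-cell tracking decoder trained by masked-image
    reconstruction, and a frame-independent residual classifier baseline.
    Includes the binary cross-entropy training objectives, the recovery
    relabeling/remapping protocol for post-mitotic frames, an evaluation suite
    (confusion matrices, precision/recall/F-score, label matrices, PCA
    embeddings, threshold segmentation of the tracker output), and a seeded
    synthetic mitosis time-lapse generator so every component is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    cluster,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
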