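Package: cddlite
Title: Lightweight One-Stage Detection of Cotton Foliar Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, profiles and evaluates a family of lightweight
    one-stage object detectors for cotton foliar disease lesions (verticillium
    wilt, fusarium wilt, anthracnose). Provides the reusable block vocabulary
    (partial convolution, C2f and C2f-Faster cross-stage blocks, GSConv and
    VoVGSCSP slim-neck fusion modules, SPPF), an anchor-free decoupled
    detection head with a partial-convolution variant (PCDetect), the MPDIoU
    bounding-box similarity and the CIoU/GIoU/SIoU/WIoU loss family,
    distribution focal loss with task-aligned assignment, COCO-style
    mAP evaluation, a parameter/FLOP cost profiler with a pinned counting
    convention, YOLO-dialect dataset input/output with mosaic augmentation and
    letterboxing, a synthetic lesion-image generator, and a desk-scale
    training loop. A command-line interface ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
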