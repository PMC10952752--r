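Package: fetaltrack
Title: Closed-Loop Fetal Brain Tracking and Prospective FOV Correction for Dynamic MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of prospective
    motion correction for functional fetal MRI: synthetic acquisition of
    EPI-like dynamic volumes of a moving object (sphere phantom or
    fetal-head-like scene with a confounding abdominal blob), automatic
    target localization by intensity-based segmentation or a natively
    implemented 3D U-Net trained with the generalized Dice loss,
    center-of-mass displacement estimation between repetitions n and n-2,
    field-of-view recentering with two-repetition latency, and quantitative
    evaluation (Dice, IoU, per-axis center-of-mass MSE) with grouped
    summaries. Audit trails, metrics and training histories are tibbles with
    tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
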