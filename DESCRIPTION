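Package: microflow
Title: Automated Two-Step Analysis of Microvascular Blood Flow in
    Intravital Video Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated functional analysis of capillary perfusion in
    brightfield intravital video microscopy (IVM). A temporal
    sum-of-absolute-differences (SAD) image highlights vessels carrying
    moving red blood cells; frames with tissue motion are rejected by
    block matching; a Steger-style curvilinear ridge detector segments
    vessel-like structures; and a small spatio-temporal 3D convolutional
    network classifies each vessel/reference-line intersection as
    perfused or not, with a logistic-regression baseline for comparison.
    Includes a synthetic phantom generator with per-vessel ground-truth
    flow labels so the full pipeline can be validated without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
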