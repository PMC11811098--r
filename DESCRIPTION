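Package: blinkr
Title: Blink Kinematics from Eyelid-Region Segmentation of Ocular Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes spontaneous blinking from short ocular-surface
    video recordings. Frames are segmented into the interpalpebral
    (eyelid-to-eyelid) region with a U-Net style convolutional network, the
    per-frame open/closed state is verified with a hierarchical
    windowed-attention image classifier whose "closed" calls zero out
    spurious aperture heights, and the resulting interpalpebral-height
    percentage (IPH%) time series -- the blink wave -- is parsed into blink
    events with a run-length rule on successive IPH% differences. Events are
    classified as complete or incomplete, split into closing, closed, and
    opening phases, and summarized as counts, the incomplete blinking rate,
    and the relative IPH%. Includes a synthetic eye-video generator with
    exact ground truth for end-to-end validation, and agreement statistics
    (Bland-Altman limits of agreement, intraclass correlation, Cohen's
    kappa, Spearman correlation, normality-screened group comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
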