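Package: fingertap
Title: Video-Keypoint Quantification and Ordinal Severity Scoring of Finger Tapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying finger-tapping performance from 21-landmark
    hand-keypoint time series, as used in video-based bradykinesia assessment.
    Provides quality control of keypoint clips (error-frame ratio and
    confidence tiers), thumb-length normalization, temporal gap repair,
    short-time-Fourier-transform hand parameters (tapping frequency, intensity,
    their per-step product and peak amplitude), 3D keypoint rotation and
    Gaussian random-crop augmentation, an ordinal MDS-UPDRS item-score
    estimator built from boundary-wise binary dilated temporal convolutional
    networks, clinical agreement metrics (MCC, acceptable accuracy, Cohen's
    kappa), a seeded severity-graded tapping simulator, and per-clip /
    left-right / longitudinal reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
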