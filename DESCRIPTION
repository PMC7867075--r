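Package: bcgsleep
Title: Sleep Stage Estimation from Head-Worn Accelerometer Ballistocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the four sleep states WAKE, REM, LIGHT and DEEP from a
    single 3-axis head-mounted accelerometer sampled at 200 Hz. The pipeline
    extracts gross-movement features (epoch mean, variance and amplitude
    spectrum of the band-fused acceleration), detects ballistocardiogram
    J waves to build a 2 Hz J-J interval tachogram, derives heart-rate
    variability features (epoch mean/variance and HF/LF band-power ratios),
    and classifies each 30-s epoch with a two-step random-forest scheme
    (WAKE vs SLEEP, then REM/LIGHT/DEEP within SLEEP using sleep-conditional
    standardization, sleep elapsed time and head rest time). Includes
    leave-one-subject-out evaluation with ROC/AUC and feature significance
    testing, plus a seeded synthetic overnight-recording generator with
    ground-truth hypnograms and beat times so the whole pipeline is testable
    without human subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    pROC,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
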