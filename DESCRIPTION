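Package: sitseg
Title: Detection and Temporal Segmentation of Sit Phases from a Single
    Ankle-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting and temporally segmenting seated
    (Sit) phases in people with Parkinson's disease from a single
    ankle-worn inertial measurement unit sampled at 50 Hz. Implements
    zero-lag Butterworth preprocessing of tri-axial accelerometer and
    gyroscope signals, sliding-window extraction of 32 mean/standard
    deviation features, percentile-based feature normalization, twin
    random-forest classifiers for postural transitions and the seated
    state with out-of-bag ensemble-size diagnostics, a rule-based merge
    algorithm gated by Walking/no-Walking segments, and an event-based
    evaluation suite (sensitivity, specificity, F-score, and onset/offset
    timing error). A bundled synthetic-cohort generator emulates trials
    of repeated sit phases, transitions, standing, and walking so the
    whole pipeline is trainable and testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
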