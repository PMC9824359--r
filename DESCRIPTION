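Package: imuqc
Title: Automatic Quality Scoring of Exercise Repetitions from Body-Worn IMU Networks
Version: 0.1.0
Authors@R:
    person("imuqc", "developers", email = "imuqc@example.org", role = c("aut", "cre"))
Description: Tools for assigning an ordinal quality score ("1", "2" or "3") to a
    single exercise repetition recorded by a network of body-worn inertial
    measurement units (IMUs). Covers the full workflow: a dataset container with
    plain-text on-disk storage, a synthetic-data generator emulating
    variable-length repetitions with class-dependent movement deviations and
    noisy multi-rater scoring, majority-vote label resolution with
    Krippendorff's alpha interrater reliability, sensor-to-segment orientation
    alignment, conversion of variable-length repetitions into a zero-padded
    windowed representation with validity masks, three CNN-LSTM network
    variants implemented natively (window-shared convolution blocks, masked
    recurrence, dense softmax head, Adam optimisation), stratified and
    leave-one-subject-out cross-validation, macro and weighted F1 metrics, and
    a seeded random hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
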