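Package: gazeindex
Title: Velocity-Threshold Gaze Event Classification and the Gaze Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies raw eye-tracker gaze samples into fixations,
    microfixations, saccades and off-screen episodes with a velocity-threshold
    (I-VT) rule, computes a per-participant suite of screen-viewing metrics
    including the Gaze Index (the ratio of time spent staring to time spent
    scanning), and runs cohort-level nonparametric group comparisons.
    Includes a calibrated synthetic gaze-stream generator that emulates
    alternating stare and reading-like scan bouts with off-screen episodes,
    so the full pipeline can be exercised and validated without access to
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest
Config/testthat/edition: 3
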