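Package: wearlc
Title: Passive Wireless Multi-Sensor Textile LC Sensing and Activity
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for passive wireless wearable
    sensing systems built from capacitive textile strain sensors tapping a
    single planar spiral inductor. Provides closed-form design formulas
    (Wheeler inductance, parallel-plate capacitance, resonance frequency,
    quality factor, inductive coupling), a small-signal solver for the
    reader-coupled multi-resonator circuit producing S11 reflection sweeps
    with dip detection and a capacitor design-space search, a seeded
    generator of synthetic two-sensor resonance-frequency recordings with
    realistic sensor artifacts (hysteresis, baseline drift, phase-dependent
    noise, inter-session shifts), and a movement-monitoring pipeline:
    zero-phase low-pass filtering, range-relative threshold phase labeling
    with two-sensor reconciliation, overlapping-window feature extraction,
    cycle-based train/validation/test splitting, and a bank of standard
    classifiers with cross-validated tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    class,
    nnet,
    rpart,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
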