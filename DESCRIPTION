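Package: hmikit
Title: Hands-Free Human-Machine Interfaces for Wheelchair Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-to-command toolkit for two hands-free assistive
    human-machine interfaces: a piezoelectric face-machine interface that
    detects eye winks, both-eye blinks and tongue pushes from three
    temple/cheek sensors sampled at 1000 Hz, and an accelerometer
    head-machine interface that detects head tilts from two-axis
    acceleration sampled at 200 Hz. Provides causal IIR preprocessing
    filters, threshold-based calibration ('fit_face_hmi', 'fit_head_hmi'),
    windowed maximum-amplitude feature extraction, a 2-second command
    pipeline emitting five-state wheelchair commands, a seeded synthetic
    signal generator standing in for human participants, per-command
    confusion-matrix metrics (success, precision, sensitivity, accuracy),
    and a minimal 2D kinematic wheelchair route simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
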