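Package: grfsync
Title: Event-Based Synchronization of Markerless Motion Capture and
    Force Platform Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Temporal alignment of markerless motion-capture heel
    kinematics with force-platform vertical ground reaction force (vGRF)
    recordings acquired without a shared hardware trigger.  Heel contact
    is detected from the min-max normalized, zero-phase Butterworth
    filtered vertical heel coordinate with an adaptive amplitude
    threshold; loading onset is detected from the low-pass filtered vGRF
    with a baseline-plus-scaled-SD threshold.  The signed offset between
    the two events re-times the force stream onto the kinematic clock.
    Includes readers and writers for TRC marker files and delimited
    force exports, 0-100 percent movement-cycle normalization, curve
    agreement metrics (Pearson r, RMSE, MAE), a quality-control flag for
    preliminary-step force transients, a deterministic synthetic-trial
    generator with known injected clock offsets, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
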