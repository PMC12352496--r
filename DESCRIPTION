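Package: dsokr
Title: Quantification of Retinal Direction Selectivity and the Optokinetic Reflex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for cellular neurophysiology and visuomotor
    behaviour: direction-tuning statistics (vector sum, direction
    selectivity index) from patch-clamp sweeps, a single-compartment
    parallel-conductance membrane model integrated by forward Euler,
    IV-curve conductance and reversal-potential estimation from paired
    recordings with an R-squared quality gate, convex-hull dendritic
    overlap geometry, and optokinetic reflex gain from two-camera
    pupil-marker tracking (Coope circle fit, corneal-reflection
    referencing, angular calibration, saccade segmentation). Ships a
    synthetic-data generator with known ground truth for every input
    stream so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
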