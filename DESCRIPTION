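Package: hemigaze
Title: Gaze-Contingent Hemianopia Simulation and Driving-Gaze Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline toolkit for simulating homonymous hemianopia with a
    gaze-contingent moving mask on a panoramic three-panel driving-simulator
    rig, and for processing the associated gaze and driving data. Maps gaze
    direction vectors to panel pixel anchors, replays the hemifield mask with
    buffering, bypass and semitransparent fade, cleans 60 Hz gaze streams
    (head-pose fallback, region exclusion, zero-phase Butterworth filtering),
    detects fixations and saccades with dispersion and velocity thresholds,
    segments intersection approaches into deceleration phases, computes
    hemifield scanning and lane-keeping metrics, and classifies impaired-
    condition values against within-subject normal-vision bands of half the
    sample interquartile range (equal/above/below analysis). Includes a
    synthetic scanpath-and-drive study generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
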