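Package: attentrics
Title: Webcam Gaze-Based Attention Evaluation with EEG Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rule-based evaluation of an audience's visual attention from
    per-frame webcam gaze logs.  Classifies eye-movement events (fixations,
    saccades, smooth pursuits and left-to-right reading pursuits), tiers head
    poses by Euler-angle magnitude, and aggregates both into a thresholded
    indicator system (one-face frame proportion, high and medium concentration
    head-pose proportions, effective and serious fixation-time proportions,
    saccade-count variance, reading-pursuit rate, and optional region-of-
    interest gaze shares).  Includes the supporting image operators (Otsu
    thresholding, YCrCb skin masking, gradient dot-product pupil-centre
    localization), head-pose recovery from 2D-3D landmark correspondences,
    a Welch power-spectral-density EEG verification arm comparing frontal
    beta and theta band power between session halves, and seeded synthetic
    generators for gaze streams, EEG sessions and eye images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
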