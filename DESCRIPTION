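Package: tugcam
Title: Markerless Video Measurement of Timed Up and Go Subtask Speeds
Version: 0.1.0
Authors@R:
    person("tugcam", "developers", email = "tugcam@example.org", role = c("aut", "cre"))
Description: A single-camera, markerless pipeline for measuring the speed of
    the nine Timed Up and Go (TUG) subtasks from a sagittal video of a walking
    trial: background subtraction and silhouette centroid tracking, two-point
    planar pixel-to-metre calibration, windowed instantaneous speeds, and
    rule-based segmentation of the trial into sit-to-stand, three outbound
    1-metre walk segments, turn, three return segments, and stand-to-sit.
    Includes the motion-capture reference computation (zero-phase Butterworth
    filtering and four-marker pelvis centre of mass), concurrent-validity and
    test-retest agreement statistics (Pearson r with interpretation bands,
    ICC(3,2) with confidence intervals, Bland-Altman limits of agreement), and
    a synthetic trial generator that renders silhouette video and matched
    marker tracks with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
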