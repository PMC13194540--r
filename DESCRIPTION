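Package: climbkit
Title: Kinematics and Interlimb Coordination Analysis for Climbing Mice
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing ventral-view markerless
    pose-estimation tracks of mice climbing a vertical grid wall. Reads
    per-frame keypoint tables, segments paw reach/grasp events and slips from
    speed-thresholded trajectories, computes per-stride gait metrics (reach,
    step and stride lengths, step width, duty factor) with body-speed binning,
    quantifies interlimb coordination via directed phase offsets and the
    Jaccard temporal-overlap index, and provides the circular statistics
    (Rayleigh test, Watson-Williams test, circular-linear regression) and
    mouse-level mixed-model inference used to compare limb pairs, speeds and
    wall locations, including a gap-crossing wall variant. A synthetic climb
    simulator with full ground truth supports validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
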