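Package: quickreba
Title: Automatic REBA Scoring of Working Postures from 2D Skeleton Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes Rapid Entire Body Assessment (REBA) scores and
    musculoskeletal-disorder risk levels from 2D human skeleton keypoints,
    such as those produced by convolutional-pose-machine estimators
    (OpenPose-style JSON or plain CSV). Implements limb-angle kinematics
    with a vertical reference frame, bilateral max reduction, and automatic
    posture heuristics (trunk/neck twist from exposure ratios, single-leg
    and kneeling support, gravity-assisted upper arm, shoulder elevation,
    wrist twist), the full REBA table chain with load, coupling and
    activity modifiers, and the agreement-statistics battery used to
    validate such systems against motion capture and expert raters (RMSE,
    Spearman's rho, intraclass correlation, proportion agreement, linearly
    weighted Cohen's kappa, paired t-test). A forward-kinematic generator
    of noisy synthetic working postures supports end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
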