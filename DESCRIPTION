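Package: glenosim
Title: Glenohumeral Joint Stability and Muscle Recruitment Under Simulated Rotator Cuff Tears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates glenohumeral joint stability and compensatory scapulohumeral
    muscle forces during activities of daily living under rotator cuff tears of
    graded severity. Ships a simplified eight-muscle shoulder model with
    posture-dependent moment arms and lines of action, a static-optimization
    muscle recruitment solver that minimizes the sum of cubed muscle load ratios
    subject to moment equilibrium and an elliptical glenoid containment
    constraint on the joint reaction force, a synthetic motion-capture cohort
    generator, and a repeated-measures statistical pipeline (Shapiro-Wilk gated
    RM-ANOVA/Friedman omnibus tests, Bonferroni-corrected post hoc comparisons,
    and delta-correlation classification of compensatory muscles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
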