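Package: arnav
Title: Augmented-Reality Endoscope Navigation Geometry and Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry pipeline for augmented-reality surgical navigation with an
    optically tracked endoscope: rigid-transform algebra over named coordinate
    frames, a distorted pinhole camera model with planar (Zhang) intrinsic
    calibration, perspective-three-point camera pose estimation, hand-eye
    calibration between a tracked endoscope marker and the camera, rigid
    point-set registration with motion compensation against a virtual reference
    grid, a virtual rig simulator (grid phantom, calibration targets, noisy 3D
    marker sensor, endoscope image rendering), and a target-registration-error
    (TRE) evaluation protocol with summary statistics, spatial error maps and
    one-way ANOVA with Tukey-Kramer post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
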