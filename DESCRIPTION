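Package: kneekin
Title: Polynomial Coupling Models of Tibiofemoral and Patellofemoral Kinematics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the kinematic coupling of the knee-joint
    complex. Secondary motions of the tibia and patella are described as
    polynomial functions of one or more tibiofemoral input rotations
    (flexion alone, or flexion plus external tibial rotation). The package
    ships reference coefficient sets for packaged 1-DOF and 2-DOF models,
    fits new models to pooled multi-activity kinematic time series by
    least squares, scores them with joint-level root-mean-square residual
    metrics, and validates them by leave-one-participant-out
    cross-validation. It also constructs anatomical bone frames from
    surface geometry (cylinder, cone and inertia fits), converts between
    bone pose pairs and joint-coordinate-system parameters, preprocesses
    gait trials (zero-phase Butterworth filtering, time normalization,
    bicondylar-width scaling of translations), and generates synthetic
    cohorts and bone surfaces with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
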