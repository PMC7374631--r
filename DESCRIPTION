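Package: jumpwork
Title: Work-Loop Energetics of Countermovement and Drop Jumps
Version: 0.1.0
Authors@R:
    person("Jump", "Work", email = "maintainer@jumpwork.dev", role = c("aut", "cre"))
Description: Movement-energetics analysis of vertical jumping from force-plate and
    joint-kinematic time series. Computes whole-body centre-of-mass (COM) kinematics
    by forward dynamics from ground-reaction force, builds COM and hip/knee/ankle
    work loops, decomposes negative/positive/net mechanical work and
    negative-to-positive work ratios, forms group ensemble curves and runs
    sex-by-jump and strength-tertile-by-jump comparisons. Includes a physics-based
    torque-driven planar jump simulator that generates countermovement and drop-jump
    trials with known ground-truth joint torques, so the whole pipeline is testable
    without any experimental data, plus zero-lag Butterworth filtering, planar
    bottom-up Newton-Euler inverse dynamics, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
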