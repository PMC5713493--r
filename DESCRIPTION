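Package: stairgait
Title: Foot-Mounted IMU Analysis of Stair Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates foot orientation, velocity and trajectory during stair
    running from a foot-mounted inertial measurement unit (tri-axial
    accelerometer and gyroscope). Orientation is obtained by quaternion
    strapdown integration fused with accelerometer tilt observations in a
    Kalman filter; velocity and position follow from double integration with
    zero-velocity updates (ZUPT) during the stance phase and an additional
    single-state Kalman correction of foot elevation against the known stair
    riser height. Foot-strike and toe-off are detected from high-frequency
    wavelet content, and per-stride timing, kinematic and kinetic performance
    metrics (stance/swing/stride times, foot clearance, kinetic-energy and
    ground-reaction-force proxies, pitch bounce angle) are computed and
    summarised with simple linear regressions and condition contrasts. A
    synthetic stair-running IMU simulator provides ground truth for testing
    every processing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
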