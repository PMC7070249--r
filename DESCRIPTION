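Package: imugait
Title: Wearable Inertial-Sensor Gait Analysis with Zero-Velocity Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strapdown inertial gait analysis for foot- and shank-mounted IMUs.
    Integrates attitude by fourth-order Runge-Kutta quaternion propagation,
    detects stance phases with an adaptive windowed detector, removes
    integration drift with per-cycle zero-velocity updates, segments gait
    cycles with a k-means duration filter, and reports seven clinical gait
    parameters (cadence, stride length, gait speed, max foot elevation, ankle
    range of motion, stance ratio, bilateral gait symmetry) against reference
    ranges. Includes a Kalman-filter estimator of the IMU mounting position
    along a limb segment and a synthetic walking-trial simulator with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
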