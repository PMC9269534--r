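Package: elbowkin
Title: Upper-Limb Joint Kinematics from Wearable Inertial-Magnetic Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms raw nine-channel inertial-magnetic sensor streams
    (tri-axial accelerometer, gyroscope and magnetometer worn on the arm and
    forearm) into clinician-readable elbow kinematics: flexion-extension and
    forearm pronation-supination angle series and range-of-motion summaries.
    Provides static-pose sensor-to-segment calibration, quaternion attitude
    fusion with gyro-bias tracking, a synthetic two-sensor capture simulator
    with ground-truth angles, readers and writers for the plain-text sensor
    and optical-reference dialects, and a two-system RMSE validation
    workflow with cross-correlation time alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
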