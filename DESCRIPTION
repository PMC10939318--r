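Package: stridewise
Title: Stride-Level Gait Analysis from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete, openly testable pipeline for gait analysis with one
    inertial measurement unit (IMU) per foot: standardized sensor/body/world
    coordinate frames and units, stride segmentation by subsequence dynamic
    time warping against a stride template, gait-event detection (terminal
    contact, initial contact, mid-stance) from gyroscope and accelerometer
    signal features, zero-velocity (ZUPT) detection, trajectory
    reconstruction by gyroscope strapdown integration, Madgwick sensor
    fusion, dedrifted double integration and a ZUPT-aided error-state
    Kalman filter with Rauch-Tung-Striebel smoothing, per-stride
    spatio-temporal parameters, a tolerance-based evaluation harness with
    grouped cross-validation, and a synthetic gait simulator that provides
    exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
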