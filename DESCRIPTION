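Package: romexam
Title: IMU-Based Joint Range-of-Motion Examination and Reliability Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Magnetometer-free processing chain for inertial-sensor joint
    range-of-motion (RoM) examination: strapdown gyroscope integration with
    gravity-based tilt correction, neutral-posture sensor-to-segment
    calibration, Grood-Suntay joint coordinate system angle decomposition,
    and min/max RoM extraction over a 40-angle whole-body examination
    catalog. Includes the accompanying reliability layer (within-repetition
    standard deviations, ICC(3,k), Bland-Altman limits of agreement,
    reference-range validity flags) and a synthetic examination simulator
    that emits IMU streams and examiner rating sheets with controlled
    between-subject, within-subject, and rater error structure, so the whole
    chain is testable without hardware or subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
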