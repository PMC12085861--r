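Package: palmrod
Title: Coconut Palm Growth Modelling and Climbing-Robot Sensor Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Growth model for coconut palms built on a growing Cosserat rod:
    primary (apical) growth steered by gravitropism, sunlight and wind through
    tropism-driven initial curvature and a small-deflection apical system, and
    diffuse secondary growth as an exponential trunk taper anchored at the
    diameter at breast height (DBH). Includes a cantilever wind-load model on
    a conical-frustum trunk, a deterministic growth simulator with comparison
    metrics (variance, MAE, RMSE, R^2), and a processing chain for
    climbing-robot sensor logs: Daubechies wavelet denoising with SURE
    thresholding, extended Kalman filter fusion of 9-axis IMU data, ultrasonic
    trunk-diameter extraction, and anomaly rectification (Hampel and isotonic
    filtering). A seeded synthetic-data generator emulates climber traces and
    noisy growth observations so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
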