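Package: pape
Title: Personal Air Pollution Exposure from Wearable Body Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates personal air pollution exposure (inhaled pollutant
    dose) from multi-rate wearable sensor streams. Provides a seeded
    synthetic-data generator for body-sensor-network walking sessions
    (environmental monitor at one sample per 24 s, physiological streams at
    10 Hz), a preprocessing chain (1 Hz resampling, timestamp segmentation
    into static and dynamic microenvironment arrays, length normalization at
    3 samples per minute), a personalized minute-ventilation power model
    driven by pulse rate, respiratory rate and biometrics, trapezoidal
    concentration-time aggregation with inhaled-dose computation, a
    fixed-station "Standard Method" comparator, and the paired and
    nonparametric statistics used to compare the two dose estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
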