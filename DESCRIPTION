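Package: coilrate
Title: Heart and Respiration Rate Extraction from a Single Wearable
    Inductive Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for cardiorespiratory monitoring with a single
    textile-integrated planar inductive coil read by an inductance-to-digital
    converter. Separates a raw 20 Hz inductance-count stream into a
    respiration component (7th-order 1 Hz Butterworth low-pass) and a cardiac
    component (delay-compensated difference using correlation and average
    magnitude difference function alignment), estimates beats per minute per
    analysis window by autocorrelation with physiologic lag bounds, and
    supports validation against a reference single-lead ECG through a
    Pan-Tompkins-style QRS detector, rule-based pre-diagnosis alerts, and
    Bland-Altman agreement statistics. Includes a synthetic-data generator
    standing in for the sensor hardware, readers and writers for the plain
    text sample streams and the RestingECG XML dialect (with CRC-32
    verification), and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
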