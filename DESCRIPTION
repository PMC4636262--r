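Package: firstflight
Title: Degree-Day Modeling and Calibration of Insect First-Flight Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for linking point observations of insect first-flight dates
    to gridded daily temperatures through threshold-based cumulative
    degree-days. Computes daily degree-day contributions with a four-branch
    weighted formula, accumulates them per grid cell and regional average,
    calibrates a species-specific degree-day constant (DD_C) and base
    temperature (T_0) by root-mean-square-error grid search under two
    contrasting interpretations of citizen-science sighting scatter (spatial
    variability vs observation bias), and projects first-flight change between
    climate periods. Includes a synthetic gridded-climate and sighting-process
    generator with known truth for end-to-end verification.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
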