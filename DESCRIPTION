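Package: heatloop
Title: Thermal Challenge and Recovery Analysis for Feedlot Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for climate-controlled thermal-challenge
    experiments in feedlot cattle. Computes the temperature-humidity index
    (THI) and diurnal climate programs, cleans and aggregates telemetric
    rumen-temperature and observer physiology records to per-animal daily
    means, fits the battery of linear relationships between rumen
    temperature and heat-load indicators, and characterizes the elliptical
    (hysteresis-loop) relationship between rumen temperature and dry-matter
    intake via direct ellipse-specific least-squares conic fitting. Includes
    a seeded synthetic cohort generator emulating a paired thermally
    challenged / feed-restricted thermoneutral design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
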