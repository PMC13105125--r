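Package: homecagr
Title: Analytics for Continuous Home-Cage Behavioral Monitoring of Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing the raw data streams produced by automated
    rodent home-cage monitoring systems: operant nose-poke and dispense event
    logs, running-wheel rotary-encoder voltage traces, and video-scorer
    ethograms. Implements wheel bout segmentation from absolute-encoder
    voltage, dispense refractory (timeout) logic, quality-control flagging and
    masking of hourly count series, zeitgeber-time binning at minute, hour and
    day scales, circular statistics (mean resultant vector) for circadian
    phase estimation, ethogram time budgets, and swap-schedule-aware analysis
    separating content preference (sucrose vs regular water, fatty vs regular
    food) from place preference. Ships a synthetic home-cage simulator that
    writes all raw stream formats with known ground truth so each analysis
    stage can be validated end to end, plus a reproducible pipeline with tidy
    spreadsheet exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
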