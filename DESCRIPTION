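Package: rollchrom
Title: Cell Adhesion Chromatography of Rolling Cells in Microchannels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, tracks, and analyses pulses of cells transiting a
    selectin-functionalized microchannel under shear flow. Cells stochastically
    switch between a slow rolling-adhesion state and a fast free-flow state; a
    two-state continuous-time model generates ground-truth transits that can be
    rendered as noisy time-lapse image stacks. A running-average background
    tracker turns image stacks into track tables, and a chromatography module
    computes elution-based metrics: rolling fraction, instantaneous and average
    velocities, residence-time distributions, and mass-balance percent binding
    time, plus regression and dose-response summaries for comparing cell
    subtypes and adhesion antagonist doses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
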