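Package: plungedee
Title: Daily Energy Expenditure of Plunge-Diving Seabirds from Doubly
    Labelled Water and Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate daily energy expenditure (DEE) in
    plunge-diving seabirds by combining single-sample doubly labelled
    water (DLW) energetics with biologging. Implements vectorial dynamic
    body acceleration (VeDBA) from 50 Hz tri-axial accelerometry,
    per-minute behavioural data streams (colony presence, wingbeat
    frequency, dive fraction, step length), a four-state hidden Markov
    model classifier (colony, commuting, foraging, resting), one-pool
    DLW calculations (isotope turnover, dilution spaces, CO2 production,
    energy conversion), daily standardization, time budgets, and an
    AICc-ranked candidate set of time-budget and DBA models of
    mass-specific DEE with activity-specific metabolic rates. Includes a
    synthetic biologging cohort simulator with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
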