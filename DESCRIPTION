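Package: triagesim
Title: Simulated Physiological Signals and Rule-Table Emergency Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates synthetic electrocardiogram waveforms and low-rate
    vital-sign ("numerics") streams, extracts the classic fiducial-point
    features (R, Q and S locations, QRS width, ST-segment elevation,
    beat count and peak-to-peak regularity), summarises numerics channels
    into vital-feature rows, and enumerates symptom-by-vitals patient
    cohorts that are classified into ordered emergency triage levels
    (Normal, Cold State, Sick, Urgent, Risk) by an exact-fit rule model
    induced from a packaged 580-patient ground-truth table. Tidyverse
    interfaces throughout: data frames in, tibbles out.
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
    withr
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
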