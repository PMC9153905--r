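Package: sstsim
Title: Simulation, Scoring and Analysis of the Web-Based Stop-Signal Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulatable engine for the adaptive-staircase stop-signal task
    (SST) together with the complete scoring, exclusion and statistical
    pipeline used to validate web-based administrations of the task.
    Simulates cohorts of synthetic participants under the independent
    horse-race model (ex-Gaussian go process racing a Gaussian stop process),
    runs the 1-up/1-down stop-signal-delay staircase, scores the full
    session-level variable battery (go accuracy, omissions, errors, go RT,
    intraindividual SD, stop accuracy, mean programmed and clock-measured
    SSD, failed-stop RTs, and mean-method SSRT), applies the standard
    participant-level exclusion rules, and analyses two-condition
    within-subject designs with paired t tests, Cohen d_z, Fisher-z
    correlation intervals, Welch t tests, Fisher exact tests and the JZS
    (Cauchy-prior) paired-sample Bayes factor.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
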