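Package: esmlag
Title: Lagged Dynamics of Daily Sleep and Symptom Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for intensive longitudinal self-report data collected as
    once-daily sleep and symptom diaries. Provides a synthetic diary
    generator with known cross-lagged dynamics, cleaning and composite
    scoring of diary items, person-centred standardization, construction of
    calendar-aligned lag designs, a two-stage exploratory-confirmatory
    time-varying lag model (penalized-spline screening of a smooth lag
    coefficient function followed by a state-space vector-autoregressive
    confirmatory fit with a missing-data-tolerant Gaussian likelihood),
    auto-regression analyses, and lag-space mediation analysis with joint
    significance testing and BIC model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
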