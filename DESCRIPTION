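Package: wardflow
Title: Next-Day Ward Discharge Forecasting from Administrative Patient-Flow Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for forecasting the number of next-day
    discharges from a hospital ward using only administrative data (no
    real-time clinical information). Includes a seeded discrete-event
    simulator of ward patient flow, ingestion of the three-table hospital
    schema (patients, ward stays, admissions) into daily
    discharge/admission/occupancy series, construction of a 108-column
    predictor matrix (20 ward-level and 88 patient-level features), three
    naive baselines and a pattern-matching k-nearest-neighbour forecaster
    implemented from scratch, ARIMA/ARMAX and random-forest /
    support-vector-regression adapters with rolling one-step-ahead
    evaluation, and the standard forecast error metrics (MFE, MAE, RMSE,
    sMAPE) with per-weekday breakdowns and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    ranger,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
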