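Package: icugrud
Title: In-Advance Prediction of ICU Deterioration Events from Irregular
    Time Series with Decay-Based Recurrent Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time, in-advance prediction of clinical
    deterioration events (such as pressure ulcers) from hourly intensive-care
    time series with extreme missingness. Implements the full pipeline:
    long-format event tables to hourly per-patient grids with observation
    masks and time-since-last-observation, IQR outlier fencing, min-max
    scaling, forward-then-mean filling, per-timestep in-advance labels,
    GRU-D and GRU-D++ recurrent classifiers with learned decay-based
    imputation (trained end-to-end by backpropagation through time in
    compiled code), horizon AUROC/AUPRC evaluation, sampling-based Shapley
    variable ranking, external-cohort rescaling and fine-tuning, and a
    synthetic ICU cohort generator so every stage is testable without
    access to protected clinical data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
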