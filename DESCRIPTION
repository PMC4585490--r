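Package: errcmeg
Title: Multiple Linear Regression Analysis of Epoched MEG Data with
    Minimum-Norm Source Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-univariate multiple linear regression of epoched
    magnetoencephalography (MEG) data on item-level psycholinguistic
    predictors. Builds standardized composite predictors from norm tables
    via correlation PCA, computes event-related regression coefficients
    (ERRCs) per channel and latency, summarizes multichannel responses as
    the RMS of signal-to-noise ratios, estimates cortical sources of the
    coefficients with a regularized L2 minimum-norm inverse operator and
    dSPM noise normalization, and performs bias-corrected region-of-interest
    group statistics. A synthetic-data generator simulates multi-subject
    sensor arrays with known predictor-scaled source effects so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
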