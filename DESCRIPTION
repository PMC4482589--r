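Package: fireclim
Title: Time-Varying Fire-Climate Relationship Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting changing relationships between climate and
    annual area burned. Summarizes daily fire-danger and water-balance
    metrics into annual fire-season predictors (with an optimal-window
    search), fits moving-window regressions of log annual area burned with
    coefficient-of-efficiency (CE) cross-validation skill, ranks candidate
    predictors, builds Monte-Carlo null-model envelopes for time-varying
    statistics under a constant-relationship null, locates fire-activity
    change points by piecewise linear regression on the cumulative log
    series, and compares climate metrics among discrete periods with
    rank-based tests robust to serial autocorrelation (block bootstrap).
    Includes a synthetic-data generator with known truth for regime-shift
    scenario experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
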