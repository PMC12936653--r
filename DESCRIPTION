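Package: raapscan
Title: Geospatial Disparity Analysis of Risk-Adjusted Antiemetic Prophylaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting neighborhood-level disparities in perioperative
    antiemetic prophylaxis. Classifies surgical patients by risk-adjusted
    antiemetic prophylaxis (RAAP) relative to peers in the same postoperative
    nausea and vomiting (PONV) risk stratum, detects geographic clusters of
    under-treatment across census block groups with a Poisson spatial scan
    statistic (circular windows, likelihood-ratio maximization, Monte Carlo
    inference), and characterizes detected clusters with contingency tables,
    logistic regression on neighborhood covariates, and Moran's I on model
    residuals. Includes a synthetic cohort and geography generator with a
    planted under-treatment cluster for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
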