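Package: heatsmoke
Title: Joint Effects of Extreme Heat and Wildfire Smoke on Hospitalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the joint (additive and multiplicative)
    effects of compound wildfire smoke and extreme heat exposure on
    hospitalizations with a time-stratified case-crossover design.
    Builds ZCTA-level daily exposure series (wildfire-influenced PM2.5
    via smoke-free baseline subtraction under satellite plume masks,
    population-weighted aggregation, month- and ZCTA-specific percentile
    heat thresholds), constructs matched case-crossover strata with
    lag-assigned exposures, fits the conditional logistic interaction
    model by exact conditional maximum likelihood, and derives additive
    interaction measures (RERI, attributable proportion) with
    delta-method confidence intervals across a 4x4 grid of exposure
    lags. Includes a synthetic-data generator with known ground truth
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
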