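Package: heatmort
Title: Heat-Related Mortality Analysis with Case Time Series and
    Distributed Lag Non-Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the short-term effect of heat on daily
    mortality in small-area (municipal) panels and projecting it under
    climate-change scenarios. Implements the case time series design: a
    conditional Poisson regression with stratified baselines, a
    temperature-by-lag cross-basis (distributed lag non-linear model),
    minimum-mortality-temperature estimation, forward attributable
    fraction and number computation with Monte Carlo empirical confidence
    intervals, trend-preserving bias correction of climate-model
    temperatures, and end-of-century excess-mortality projections.
    Includes a synthetic-data generator with a known exposure-lag-response
    surface so that the whole pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
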