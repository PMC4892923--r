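Package: heatclock
Title: Hour-by-Hour Temperature Exposure Metrics and Heat-Mortality
    Relative Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds daily heat-exposure variables from sub-hourly weather
    station records (24 top-of-hour snapshots plus seven daily summary
    metrics such as max, min and three formulations of the daily mean),
    fits an overdispersed count-regression model with fixed-df regression
    spline terms for long-term time trends and temperature to daily
    all-cause death counts, and estimates percentile-contrast relative
    risks (99th vs. 85th percentile of each exposure variable, lags 0-3)
    with confidence intervals, generalized cross-validation diagnostics,
    and subset correlation reports.  Includes a synthetic-city generator
    (seasonal and diurnal temperature cycles, AR(1) anomalies, heat
    waves, overdispersed mortality counts with a configurable injected
    temperature effect) so the whole pipeline can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
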