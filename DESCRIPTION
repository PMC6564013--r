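Package: tempadmit
Title: Two-Stage Distributed Lag Non-Linear Modelling of Temperature and
    Hospital Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate short-term associations between daily ambient
    temperature and cause-specific hospital admission counts across many
    provinces. Implements province-level quasi-Poisson time-series regression
    with a distributed lag non-linear cross-basis (quadratic B-spline in
    temperature, natural cubic spline in lag up to 21 days), reduction to the
    overall cumulative exposure-response association, multivariate
    random-effects meta-analysis with REML and best linear unbiased
    predictions, location of the minimum-hospitalizations temperature
    percentile, percent-change effect estimates at extreme percentiles,
    Wald-type comparison of calendar periods, and heat-wave /
    prevention-plan-activation indicator analyses. A synthetic multi-province
    data generator with a known exposure-lag-response surface supports
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    metafor,
    yaml,
    jsonlite
Suggests:
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
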