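Package: concsim
Title: Concentration Index and Simulated Confidence Intervals for
    Aggregated Register Data
Version: 0.1.0
Authors@R:
    person("Register Inequality", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Measures socioeconomic inequality in health outcomes from
    aggregated total-population register data using the concentration
    index on directly age-standardized rates.  Provides the arithmetic
    and weighted-least-squares estimators of the index, the concentration
    curve, conventional regression-based and serial-correlation-corrected
    analytic confidence intervals, and five Monte Carlo percentile
    interval procedures that model the registration error structure of
    count data (normal perturbation of the regression outcome, normal
    perturbation of age-adjusted rates, and binomial, Poisson and
    multinomial resampling of death counts).  Includes a machine-readable
    rule set for classifying deaths amenable to health care by ICD-10
    code and age, and a synthetic register generator with a calibrated
    Finnish-style preset for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
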