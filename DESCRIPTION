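Package: epftherm
Title: Thermal Performance Modeling and Climate Suitability Mapping for
    Entomopathogenic Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Ratkowsky-family thermal performance curves to fungal
    growth and virulence data, fits cumulative time-mortality models
    (logistic, log-logistic, log-normal, Weibull, Gompertz), estimates
    median lethal times (LT50) with bootstrap confidence intervals, and
    projects fitted temperature responses onto gridded monthly climate
    (ESRI ASCII and flat-binary rasters) to classify biocontrol
    performance. Includes a synthetic-data module generating colony
    growth trajectories, binomial mortality time courses, and monthly
    climate stacks for end-to-end validation. Motivated by biocontrol of
    the whitefly Bemisia tabaci with Cordyceps javanica.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
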