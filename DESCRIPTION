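Package: radonmbe
Title: Mass-Balance Estimation of Mean Annual Indoor Radon Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic estimation of mean annual indoor radon
    concentrations from geography, building characteristics and
    meteorology. Implements a three-compartment mass-balance model of
    indoor radon with a closed-form steady state, a meteorology-driven
    ventilation-rate model, the invertible infiltration factor linking
    measured concentrations to radon entry rates, and a four-stratum
    linear regression that predicts the infiltration factor from district
    greenery, district radon levels and building traits. Ships a
    synthetic-data generator calibrated to published stratum summaries so
    the full inference chain (invert, fit, predict) can be exercised and
    validated without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
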