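Package: peatvpd
Title: Vapor Pressure Deficit Effects on Vegetation Growth in Northern Peatlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse whether warming-induced increases in atmospheric
    vapor pressure deficit (VPD) suppress vegetation growth, with an emphasis on
    northern peatlands. Provides closed-form meteorological and ecophysiological
    computations (saturation vapor pressure, VPD from relative humidity or actual
    vapor pressure, inverted Penman-Monteith canopy conductance, underlying
    water-use efficiency, growing-season masks); per-pixel detrended partial
    correlation mapping of gross primary productivity against VPD with climatic
    covariates, significance mapping and regional aggregation along peatland-extent
    and aridity gradients; warming-experiment analysis (paired tests with normality
    screening, exponential temperature-VPD fitting, simulated VPD contrasts,
    growth-response regression); random-forest perturbation sensitivity of VPD
    effects to soil and plant-trait predictors; serial two-mediator mediation
    models with bootstrap intervals; and seeded synthetic-data generators with
    known ground truth so the full pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
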