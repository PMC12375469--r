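Package: potatosim
Title: Water-Driven Potato Growth Simulation and Irrigation Scenario Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily water-driven crop simulation engine for potato under
    humid-temperate conditions: a layered soil-water balance with
    saturation-excess runoff and cascade drainage, canopy cover growth and
    senescence in thermal time, water-stress coefficients, normalized
    water-productivity biomass accumulation and harvest-index yield
    formation.  Includes a seeded stochastic weather generator with FAO-56
    Penman-Monteith reference evapotranspiration, field-capacity threshold
    irrigation scheduling, model-evaluation statistics (RMSE, MBE, index of
    agreement, Nash-Sutcliffe efficiency), crop water productivity, and
    multi-year wet/normal/dry scenario grids with log-response-ratio
    trade-off quadrants and stage-correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
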