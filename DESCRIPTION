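Package: pollensim
Title: Taxon-Level Pollen Emission Simulation and Climate-Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates daily wind-dispersed pollen emission fluxes for North
    American taxa from gridded daily temperature and precipitation. Pollen
    season timing is a Gaussian in day of year whose start and end dates are
    linear functions of the previous-year annual average temperature (PYAAT);
    annual production scales exponentially with PYAAT, days with precipitation
    above 5 mm are removed, and a CO2 fertilization switch doubles production.
    Includes a synthetic gridded-weather and pollen-count generator, ordinary
    least squares calibration of the phenology and production regressions,
    climate-scenario projection diagnostics (season shifts and categories,
    emission maxima and annual totals, regional and multi-member ensemble
    aggregation, land-cover differencing), and a Morris elementary-effects
    sensitivity screen of the nine model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
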