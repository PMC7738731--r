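Package: pupgrowth
Title: Neonatal Puppy Growth Curves and Weight-Series Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and monitoring puppy growth during the
    neonatal period (birth to three weeks) with the log-quadratic growth
    law P = P0 * exp(b1*x - b2*x^2). Fits the shared-slope
    indicator-variable regression that estimates the global coefficients
    from multi-puppy daily weight series, selects the polynomial order,
    and reports residual diagnostics. Describes each puppy's series as an
    ordered sequence of growth curves with strictly decreasing day-0
    offsets (P0), detecting downward curve switches ("falls"). Provides
    derived growth statistics (daily gain, relative daily gain, doubling
    time, setback-adjusted P0), goodness-of-fit metrics (MARE, RMSE,
    through-origin regression), growth-chart generation, and a seeded
    synthetic-data generator calibrated to the population structure of
    breeder-recorded weight data so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
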