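Package: railpp
Title: Point Pattern Analysis of Railway Suicide Locations on Linear Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event locations constrained to a railway
    network: hotspot detection under Gaussian location uncertainty via
    displaced-grid box counting and lower-quantile ensemble images; log-linear
    inhomogeneous Poisson process fitting with the dummy-point (Berman-Turner)
    GLM device and network Voronoi quadrature weights; simulation-based model
    validation with Z-tests; network and temporal pair correlation functions
    with simulation envelopes; a constrained-realization Monte Carlo
    randomization test for the effect of psychiatric-institution proximity; and
    per-hotspot excess-risk evaluation. Includes a synthetic-data generator
    producing networks, covariate rasters, hospital tables and case patterns
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
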