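Package: bloomfleet
Title: Multi-Vehicle Adaptive 3D Mapping of Patchy Phytoplankton Blooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for adaptive three-dimensional ocean sampling with a fleet
    of autonomous underwater vehicles. Implements an on-board spatiotemporal
    log-Gaussian-process model of chlorophyll-a fluorescence, a myopic
    adaptive waypoint planner balancing predicted concentration, predictive
    uncertainty and vehicle separation, a bandwidth-constrained binary codec
    for grid-cell data exchange over satellite short-burst-data links, a
    multi-vehicle mission simulator with a synthetic patchy bloom field, and
    geostatistical validation (empirical semivariograms with spherical fits,
    candidate-distribution scoring by histogram SSE and AIC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
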