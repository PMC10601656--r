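Package: neurogait
Title: Reflex-Controlled Musculoskeletal Walking Simulation and Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamics simulation of planar human walking with a
    seven-segment, nine-degree-of-freedom skeleton driven by 18 Hill-type
    muscle-tendon units and a 37-parameter reflex controller. Episodes are
    scored with a footstep-based survival reward and the controller plus the
    12 initial-state parameters are optimized with a covariance matrix
    adaptation evolution strategy (CMA-ES). Includes gait-cycle segmentation
    and normalization, stance-normalized ground reaction forces, ensemble
    statistics, correlation against user-supplied reference kinematics, the
    self-selected-speed, speed-sweep and plantarflexor-weakness protocols,
    and a synthetic-trace generator for testing the reward and analysis
    stages without running physics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    parallel,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
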