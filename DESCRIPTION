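Package: intravasim
Title: Stochastic Cell-Based Simulation of Tumor Growth and Intravasation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional agent-based model of tumor progression in
    which cells perform a discretized persistent random walk, proliferate
    under crowding and vascular-nourishment control, become quiescent or
    necrotic when they fail to divide, and stochastically intravasate on
    contact with blood-vessel cross-sections. Includes trajectory
    statistics (root-mean-square speed, persistence ratio, four
    speed-persistence groups), spatial summary metrics (uniformity index),
    and batch drivers for speed-persistence sweeps, phenotype-mixture
    experiments, and intravasation-per-thousand-cells assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
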