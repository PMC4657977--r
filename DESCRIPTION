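Package: larvataxis
Title: Agent-Based Simulation of Drosophila Larva Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates chemotaxis of Drosophila melanogaster larvae as a
    two-segment agent whose transitions between runs, head casts and
    weathervane casts are stochastic, with transition rates modulated by
    linear kernels convolved with the normalised rate of change of odour
    concentration perceived at the head. Provides analytic odour landscapes
    (Gaussian, linear, exponential, step, gridded, with optional
    multiplicative noise), circular and rectangular arenas with wall
    handling, batch experiment protocols, and a trajectory-analysis suite:
    turn and head-cast segmentation, bearing statistics, straightness
    index, preference index and chemotaxis index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
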