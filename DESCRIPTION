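Package: hexsca
Title: Multiscale Stochastic Cellular Automata for Population Dispersal on
    Hexagonal Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spatial spread of an insect population (motivated by
    mountain pine beetle outbreaks) with a stochastic cellular automaton on a
    hexagonal lattice.  Macroscale dispersal moves population density between
    cells of an interaction neighbourhood through Bernoulli inclusion and
    colonization-survival draws; a discrete-time stochastic birth-death process
    with logistic births supplies within-cell population dynamics, coupled
    sequentially to the dispersal step.  Provides pattern statistics (boundary
    complexity, equal-area radius, centre of mass, dispersion rate) and
    consistent-Bayes stochastic-inverse-problem calibration of the dispersal
    parameters from simulated or image-derived observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
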