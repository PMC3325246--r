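Package: rtnstab
Title: Stability of Random Threshold Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for Wagner-type gene network models, a class
    of random threshold networks in which gene expression states evolve by
    synchronous iteration x(t+1) = sigma(W x(t)) of a signed interaction
    matrix through a step or sigmoid normalization. Generates random network
    ensembles under regular, Poisson and biologically motivated degree
    distributions with binary or real-valued weights, iterates the dynamics
    to their attractors with exact cycle detection in the discrete case,
    and estimates stability, the probability that a random (network, initial
    state) pair reaches a fixed point rather than a limit cycle. Includes
    exact small-network enumeration, per-matrix stability distributions,
    attractor period and transient statistics, phenotype discovery curves,
    and reproducible parameter-sweep experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
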