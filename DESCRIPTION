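Package: spinflow
Title: Information Flows and Node Roles in Noise-Induced Transitions on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact analysis of noise-induced (metastable) transitions in
    networked binary-spin systems governed by Glauber single-spin-flip
    dynamics.  Builds the full 2^n transfer operator for a kinetic Ising
    model on an arbitrary connected graph, computes stationary and
    free-energy structure over the magnetisation coordinate, derives
    per-node conditional mutual-information flow curves, integrated mutual
    information and asymptotic information, and classifies nodes as
    transition initiators or stabilizers.  Includes exhaustive enumeration
    and scoring of tipping-point trajectories, attractor-commitment
    probabilities, and a compiled Monte Carlo simulator for causal
    node-pinning interventions on Erdos-Renyi ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
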