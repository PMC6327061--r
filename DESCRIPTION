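Package: crossfeedr
Title: Costless Metabolic Secretions and Cross-Feeding Interaction Motifs
    from Constraint-Based Models
Version: 0.1.0
Authors@R:
    person("Crossfeedr", "Developers", email = "crossfeedr@example.org",
           role = c("aut", "cre"))
Description: Detects "costless" metabolic secretions in stoichiometric
    (genome-scale or toy) metabolic models with flux balance analysis and a
    parsimonious total-flux secondary objective, simulates iterative pairwise
    cross-feeding experiments over combinatorial environments, classifies the
    resulting ecological interactions into competition, commensalism and
    mutualism motifs, and assesses motif stability with a Monod chemostat ODE
    model. Ships a deterministic generator of small, analytically solvable toy
    metabolic networks used as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
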