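Package: mazeplan
Title: Planning Models for Spatial Search in Partially Observable Grid Mazes
Version: 0.1.0
Authors@R: person("Maze", "Plan", email = "mazeplan@example.org", role = c("aut", "cre"))
Description: Tools for studying spatial planning under uncertainty in the
    Maze Search Task, a grid-world search paradigm in which an agent must
    reach an exit hidden in one of several initially unobserved rooms while
    minimizing the number of steps taken. The package builds the
    observation-order decision tree of a maze, computes expected-utility
    costs together with discounted, probability-weighted, and
    numerosity-distorted variants, one-step heuristics, and a Monte Carlo
    tree search approximation; simulates softmax agents; fits models to
    decision logs by cross-validated penalized likelihood; compares model
    families; and runs decision-time regressions. Includes a synthetic-data
    generator for validated random mazes and behavioral cohorts with known
    generating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
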