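Package: fuelscape
Title: Multi-Objective Simulation-Optimization of Fuel Management in
    Multi-Ownership Forest Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design non-spatial understory-clearing rules for
    landscapes split among many independent landowners. Simulates hexagonal-cell
    cork oak landscapes partitioned into Gamma-distributed landholdings, applies
    group-structured management regimes under stochastic implementation of
    clearing intervals, and scores six landscape-level objectives (management
    cost, fuel load, fuel edge contrast, fuel concentration, and mid- and
    late-successional habitat area). An elitist nondominated-sorting genetic
    algorithm (NSGA-II) searches regime space with worst-case aggregation over
    replicate landscapes; post-processing supplies level-diagram scores,
    restriction-scenario filtering, compromise-regime re-simulation,
    kernel-density solution distances and principal-coordinate embeddings, plus
    sensitivity sweeps over landholding-area and implementation-uncertainty
    assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
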