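Package: serfc
Title: Coactivation Patterns of Excitable Networks from Structural Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the deterministic three-state susceptible-excited-refractory
    (SER) cellular automaton on undirected binary graphs and predicts the resulting
    functional connectivity (pairwise coactivation) analytically from structural
    connectivity. Provides seeded benchmark-graph generators (Erdos-Renyi,
    Barabasi-Albert, modular, and triangle-motif fixtures), a vectorized simulator
    with an exact state-space enumeration oracle for small graphs, triangle-motif
    enumeration around node pairs, four analytical predictors (normalized structural
    connectivity, topological overlap, and two pacemaker-based mean-field
    predictions), and the evaluation protocol comparing simulated and predicted
    coactivation across initial conditions, topologies, and densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    igraph,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
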