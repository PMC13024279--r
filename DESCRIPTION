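Package: tihs
Title: Topology-Integrated Hubness Scoring for Network-Based Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies node hubness on differential-expression-induced
    protein-protein interaction networks by integrating five weighted
    centrality metrics (degree, betweenness, eigenvector, maximal clique
    centrality, edge percolated component) into a single Topology-Integrated
    Hubness Score (TIHS). Overlays curated drug-target affinity tables to
    rank repurposing candidates with a signed drug sensitivity score,
    applies a multi-tier false-positive filter, and ships the full
    statistical validation suite (exact McNemar, exact binomial, bootstrap,
    permutation rank tests, chi-squared weight tests), a resistance-shift
    heterogeneity module, and a synthetic-data generator with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
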