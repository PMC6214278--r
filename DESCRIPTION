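Package: maxrd
Title: Identifying Influential Spreaders by Rank-Degree Graph Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph exploration sampling for identifying influential
    spreaders in complex networks without access to the full graph. The
    core method is maxRD, a deterministic rank-degree exploration that
    repeatedly crosses the edge to the maximum-residual-degree neighbour,
    alongside Forest Fire, Metropolis-Hastings random walk and
    Metropolis-Hastings degree-distribution samplers for comparison.
    Ground-truth node spreading efficiency is obtained from discrete-time
    SIR and SIS epidemic simulations with threshold calibration and
    equilibrium detection; candidate rankings built from degree, k-core or
    betweenness centrality on samples or on the full graph are scored with
    imprecision, persistence-distance, OSim and top-k Kendall tau
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
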