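Package: multicens
Title: Hierarchical Centrality Measures for Weighted Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes hierarchically decomposable centrality measures for
    weighted multilayer networks, designed to prioritize genes mediating
    tissue-tissue communication.  The supra-adjacency matrix of a multilayer
    network is split into an intra-layer part and an inter-layer part, and a
    family of PageRank-style fixed-point scores (local, global,
    layer-specific, local-set and query-set centrality) quantifies the
    influence of every node on the whole network, on one target layer, or on
    a query set of nodes inside a target layer.  Also provides baseline
    centralities (intra-/inter-layer degree, PageRank versatility, random
    walk with restart on heterogeneous networks), an Erdos-Renyi
    planted-community benchmark generator, multi-tissue coexpression network
    construction from expression matrices with optional protein-protein
    interaction augmentation and covariate adjustment, and
    ranking-evaluation utilities (recall-at-k, normalized area under the
    recall curve, variance-stratified random gene sets, delta ranks, and
    literature co-occurrence support scores).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
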