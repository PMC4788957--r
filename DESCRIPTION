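Package: coexnet
Title: Gene Co-Expression Network Construction, Topology and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, weighted gene co-expression networks from
    expression matrices using a hard absolute Pearson correlation cut-off
    selected by scale-free model fit, characterises network topology
    (clustering coefficient, path lengths, HITS authoritative hubs) with
    Erdos-Renyi and Barabasi-Albert null-ensemble significance tests,
    clusters genes by partition around medoids and average-linkage
    hierarchical clustering with silhouette-based model selection, performs
    dual-source Fisher's exact test term enrichment, and validates
    perturbation predictions through network neighbourhood fold-change
    shift tests. Includes seeded synthetic-data generators with planted
    correlated gene modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    cluster,
    jsonlite,
    Matrix,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
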