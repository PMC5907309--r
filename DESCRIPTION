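Package: dynamotif
Title: Incremental Motif Counting in Dynamic Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maintains motif frequencies in an undirected network as it
    evolves through edge insertions and deletions, without recounting from
    scratch. Tracks the F1 count (all embeddings of a small connected motif)
    exactly and the F2 count (a maximal set of pairwise edge-disjoint
    embeddings) via local repair rules driven by a per-edge embedding index.
    Also provides static enumeration with the min-degree greedy for
    edge-disjoint (F2) and node-disjoint (F3) embedding sets, seeded
    Erdos-Renyi, Watts-Strogatz and Barabasi-Albert network generators,
    degree-preserving edge-shuffle edit scripts, paired gene co-expression
    network construction from expression matrices, and an evaluation harness
    comparing dynamic counts against static recounts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'dynamotif-package.R'
    'graph-core.R'
    'motifs.R'
    'static-count.R'
    'dynamic-count.R'
    'netgen.R'
    'coexpress.R'
    'evaluate.R'
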