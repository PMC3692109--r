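Package: oranet
Title: Over-Representation Analysis and Hierarchical Network Module Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-list over-representation analysis (ORA) against gene-set
    collections with exact hypergeometric testing and five multiple-testing
    corrections; significance-tested hierarchical decomposition of
    protein-protein interaction networks into nested module gene sets using
    walktrap community detection and a degree-preserving edge-switching null
    model; identifier mapping; construction of reduced "enriched DAGs" of
    significant categories and their ancestors with Graphviz DOT export; and
    seeded synthetic-data generators (planted partitions, two-level
    hierarchical benchmarks, spiked ORA fixtures) plus a command-line
    interface, so every stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
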