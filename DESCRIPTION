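Package: hypernull
Title: Hyperedge-Swapping Null Models for Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of swap-based null models for hypergraphs.
    Provides a hierarchy of six degree-constrained null models generated by in-place
    hyperedge swaps on the incidence matrix (from mean-hyperdegree-preserving up to
    joint-hyperdegree- and clustering-preserving), a hyperdegree-distribution entropy
    measure of network randomness, hypergraph statistics (hyperdegrees, clustering,
    assortativity, hypertriangles and more), and two dynamical applications for
    comparing a hypergraph against its null models: greedy dismantling by nodes or
    hyperedges, and a threshold SIR contagion process on hyperedges. Includes readers
    and writers for hyperedge-list and simplex (nverts/simplices) file formats, a
    seeded synthetic hypergraph generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
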