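Package: phyloflat
Title: Flat Array-Backed Phylogenies for Ultra-Large Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Memory-minimal phylogenetic trees stored as parallel flat arrays
    with integer node identifiers assigned in depth-first pre-order, so that
    every node has a smaller identifier than all of its descendants.  Provides
    a single-pass streaming Newick reader with a constant-size input buffer and
    a matching writer, traversal iterators that reduce to index sweeps,
    most-recent-common-ancestor and patristic-distance queries that exploit the
    identifier ordering, subtree extraction, a level-order re-encoding in which
    the children of every node occupy a contiguous identifier interval, a
    dual-birth (Yule) branching-process tree simulator for generating test
    trees of arbitrary size, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
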