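Package: tcnet
Title: Generation, Enumeration and Exact Counting of Tree-Child and
    Normal Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("tcnet", "maintainers", email = "tcnet@example.org",
           role = c("aut", "cre"))
Description: Tools for rooted binary phylogenetic networks on labelled
    taxa: a validated network data structure, structural predicates
    (ancestry, incomparability, tree-child and normal class membership),
    the three rearrangement operations (leaf insertion, reticulation
    insertion, child rotation) with their reverse reduction, and
    isomorphism-free exhaustive enumeration of phylogenetic trees,
    tree-child networks and normal networks with a prescribed number of
    reticulations.  Exact integer counting is provided via recurrences
    and closed-form formulas (arbitrary-precision arithmetic, no
    floating point), together with extended Newick and edge-list
    serialization and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
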