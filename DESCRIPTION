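Package: gallhistories
Title: Labeled Histories of Rooted Binary Galled Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for rooted binary galled trees, the class of phylogenetic
    networks whose reticulation cycles (galls) are vertex-disjoint and
    non-nested. Counts the labeled histories of a galled tree - the temporal
    orderings of its coalescence and hybridization events, where a hybrid node
    is simultaneous with its two parents - by a recursive decomposition of
    each gall into its three or more descendant subtrees. Includes an
    extended-Newick reader and writer, an independent brute-force oracle that
    counts labeled histories as linear extensions of the contracted event
    poset, an exhaustive enumerator of unlabeled galled trees with few leaves,
    a gall-removal transform, and a seeded random galled-tree generator.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
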