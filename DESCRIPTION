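Package: treerec
Title: Gene Tree / Species Tree Reconciliation, Evolutionary Scenarios and
    Conditional Supertrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-based reconciliation of rooted gene trees with a rooted
    species tree. Provides the canonical last-common-ancestor (LCA) mapping
    with duplication, divergence and explicit/implicit loss inference and
    costing; a dynamic program over a time-sliced species tree that builds
    minimum-cost evolutionary scenarios including horizontal transfers (with
    or without retention of the donor copy) and gene gain through an outgroup
    lineage; a two-phase conditional supertree algorithm that assembles many
    gene trees into a species tree constrained to a clade family, with a
    reliability-weighted augmentation heuristic; and paralogous binarization
    of polytomous gene trees together with the corresponding supertree cost
    recursion. A forward simulator of gene-family evolution along a species
    tree and exhaustive small-instance enumerators support validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
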