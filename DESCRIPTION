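Package: netvc
Title: Versioned Storage, Composition and Proximity Querying of
    Context-Specific Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A version-tree extension of the compressed sparse row (CSR)
    format for storing many overlapping network versions - for example
    tissue-specific protein interaction and eQTL layers grown on top of a
    shared disease ontology, gene-disease association and generic PPI core -
    in a single set of arrays. Ancestral edge data are reused by descendant
    versions through split rows, row-set compression and key-framing, so
    that highly overlapping versions cost far less than separate CSR
    matrices.  Any stored version, or a query-time union or intersection of
    sibling versions, can be materialised as a standard CSR network and
    queried with random-walk-with-restart proximity, solved either by power
    iteration or by an accelerated Chebyshev semi-iteration.  Includes
    deterministic synthetic generators for layered tissue-specific network
    families, plain-text edge-list input, a binary container format and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
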