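Package: promkan
Title: Two-Stage Promoter Identification with a Kolmogorov-Arnold Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies bacterial promoters and classifies their strength in a
    two-stage scheme. Fixed-length DNA sequences are represented by a hybrid
    one-hot and nucleotide-chemical-property encoding and passed through a
    multi-scale one-dimensional convolutional front end, a stack of residual
    blocks whose main branch ends in a Kolmogorov-Arnold B-spline layer, and a
    Transformer-style encoder whose query, key and value projections are
    bidirectional gated recurrent units. Training minimises a regularized
    label-smoothing cross-entropy loss. The package includes the B-spline basis
    machinery with an adaptive knot-grid update, confusion-matrix metrics
    (sensitivity, specificity, accuracy, Matthews correlation), repeated
    stratified k-fold cross-validation, a seeded generator of promoter-like
    synthetic sequences, FASTA input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
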