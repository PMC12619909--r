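Package: hierTE
Title: Hierarchical Transposable Element Classification with an
    Attention-Fused Convolutional and Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transposable element (TE) sequences into the
    hierarchical Wicker-style taxonomy using one classifier per parent
    node and a threshold-stopped top-down traversal. Each node classifier
    fuses a global branch (k-mer frequencies counted with Horner's rule,
    encoded by a one-dimensional convolutional network) with a local
    branch (one-hot encoded both-end sequence, encoded by stacked gated
    recurrent units) through a learned attention mechanism. Includes
    hierarchical precision/recall/F-measure and flat multiclass metrics,
    a seeded synthetic repeat-library simulator with class-specific
    terminal motifs and composition biases, FASTA preprocessing with the
    standard length/ambiguity/duplicate filters, and stratified
    train/test splitting with upward aggregation into parent-node
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
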