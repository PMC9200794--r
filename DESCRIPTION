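Package: seqboost
Title: Gapped k-mer and Spectral DNA Features with Boosted-Tree Classification
Version: 0.1.0
Authors@R:
    person("Seqboost", "Developers", email = "seqboost@example.org",
           role = c("aut", "cre"))
Description: Binary classification of DNA sequences (e.g. disease-associated
    versus background genes) from FASTA input. Implements a 14,891-dimensional
    gapped k-mer and composition feature space, Fourier power-spectrum
    descriptors over five numerical encodings of a sequence, real-valued
    AdaBoost (SAMME.R) impurity-based feature selection, a gradient-boosted
    decision tree classifier with logistic loss and Newton leaf values, a
    seven-metric stratified cross-validation evaluator with negative-batch
    averaging, probability-based candidate ranking, and a synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
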