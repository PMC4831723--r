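Package: cdrhybrid
Title: Hybrid Chemical-Disease Relation Extraction from Parsed Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts chemical-induced disease (CID) relations from parsed
    biomedical abstracts by combining three complementary classifiers: a
    maximum-margin model over flat lexical features with a polynomial kernel,
    a maximum-margin model over shortest-dependency-path tree structures with
    subset-tree convolution kernels, and a peephole LSTM sequence model (with
    a CNN baseline) over candidate-derived token sequences. Per-candidate
    scores are calibrated through a sigmoid and merged by a convex weighted
    combination whose weights are tuned by grid search under k-fold
    cross-validation; rule-based post-processing recovers causal-pattern and
    focused-chemical relations. Includes readers and writers for the PubTator
    corpus format with CoNLL-style dependency and Penn-bracketed phrase
    parses, document-level precision/recall/F evaluation with an error
    taxonomy, and a generator of fully parsed synthetic corpora for testing
    the whole pipeline without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
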