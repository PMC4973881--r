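Package: seqdedup
Title: Supervised Duplicate Detection for Nucleotide Sequence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects duplicate pairs of nucleotide sequence database records
    with supervised learning. Record pairs are represented by 22 features
    spanning metadata similarity (description, literature, submitters),
    whole-sequence local-alignment statistics (identity, aligned proportion,
    E-value), and coding-region and translation alignment statistics. Provides
    a GenBank flat-file parser and writer, an internal Smith-Waterman
    local-alignment engine with Karlin-Altschul E-values (plus an optional
    NCBI BLAST+ backend), binary and multi-class (exact-sequence,
    exact-fragment, non-significant-alignment) classifiers built on Naive
    Bayes, decision trees and support vector machines, the Seq90 identity
    baseline, and evaluation protocols: stratified cross-validation, learning
    curves, feature-set ablation, error profiling, binary-versus-multi-class
    relative accuracy, and cross-dataset generalisation. A seeded synthetic
    corpus generator produces labelled GenBank-format record pairs for every
    duplicate class so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    jsonlite,
    optparse,
    pROC,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
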