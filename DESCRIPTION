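Package: protnoise
Title: Label-Noise Detection for Protein Subtype Classification via
    Repeated Cross-Validated SVM Vote and Decision-Value Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects likely mislabeled sequences in labeled protein datasets
    (e.g. receptor subtype annotations) by combining four alignment-free
    sequence transformations (amino-acid composition, digram frequencies,
    auto-cross covariance over z-scale descriptors, and a physicochemical
    distance-based transformation over AAindex property scales) with
    repeated cross-validated one-vs-one RBF-kernel support vector machine
    classification. Per-sequence error rates, one-vs-one voting ratios and
    cumulative pairwise decision values single out sequences that are
    consistently and confidently assigned to a class other than their label.
    An independent weighted ensemble noise-rank filter (naive Bayes, random
    forest, SVM, multi-layer perceptron) cross-validates the candidate set.
    Includes a synthetic dataset generator with controlled injected label
    noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
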