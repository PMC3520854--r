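Package: taxnbc
Title: Naive Bayesian rRNA Taxonomic Classification and Training-Set
    Congruence Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A word-based (k-mer) naive Bayesian classifier for 16S rRNA
    amplicon reads with bootstrap confidence scoring and a 60 percent
    reporting threshold; tools to build an environment-specific custom
    reference database and six-rank taxonomy (length filtering, 99 percent
    identity dereplication, nearest-cultured-hit search, genus-by-identity
    and class-level incertae sedis assignment rules); augmentation of base
    training sets with a custom database; rank-wise congruence,
    pairwise-agreement, unclassified-count and per-family mean-bootstrap
    analytics across multiple training sets; and a seeded simulator of
    hierarchical taxonomies, reference sequence families, error-bearing
    hypervariable-window reads and novel-clade holdout scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
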