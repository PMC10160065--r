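Package: dsbucket
Title: Distribution-Sensitive Bucketing for Probabilistic Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence alignment framed as statistical inference in generative
    models. Pairs of truly aligned sequences are modelled as draws from a joint
    hidden Markov model (or a pair-HMM-like sequence alignment model with
    insertions and deletions), unrelated pairs as draws from independent
    background models, and the alignment score is the log-likelihood ratio
    between the two. Search against large databases is accelerated by
    distribution-sensitive bucketing: model-optimised decision trees (HMM) and
    decision graphs (indel model) that map similar -- but not necessarily
    identical -- subsequences to shared buckets, so that only bucket
    co-occurrences need exact likelihood-ratio verification. Includes
    brute-force baselines, simulators for HMM pairs and long noisy reads, an
    evaluation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
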