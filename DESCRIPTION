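Package: casguide
Title: Cross-Variant CRISPR/Cas9 sgRNA Activity Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts CRISPR/Cas9 single-guide RNA (sgRNA) on-target
    activity jointly from the guide sequence and the Cas9 variant protein
    sequence. Provides construction of Cas9 variant proteins from
    point-mutation specifications, a dual-path convolutional encoder for
    59-nt guide records, a multi-scale TextCNN over per-residue protein
    embeddings with a pluggable embedder backend, dynamic gated fusion of
    the two representations with a trainable regression head, Spearman
    evaluation with variant-specific/cross-variant and deployment-scenario
    protocols, a 175-feature handcrafted guide descriptor including
    nearest-neighbour melting temperatures, position-wise binomial motif
    enrichment, and a seeded synthetic-data generator with planted,
    recoverable signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
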