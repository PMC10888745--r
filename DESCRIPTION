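Package: sigconnect
Title: Transcriptome Signature Matching with Rank-Based Connectivity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the mechanism of action of a compound from
    its transcriptome signature. Computes per-gene fold changes and
    differentially expressed gene (DEG) sets from replicated treated/control
    expression matrices, matches the resulting query signature against an
    L1000-style reference library of 978 landmark genes using the Zhang
    rank-based connectivity score in [-1, 1], ranks candidate drugs across
    cell lines, extracts inhibitor/antagonist target proteins from a
    drug-target table, and performs hypergeometric over-representation
    analysis on gene-set collections. Includes seeded synthetic-data
    generators (planted DEGs, planted mimic/reverser perturbagens) so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
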