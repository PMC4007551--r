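Package: lspanel
Title: Lineage-Specific Paralog Retention After the Teleost Genome Duplication
Version: 0.1.0
Authors@R: person("R.", "Carvalho", email = "rcarvalho@example.org",
    role = c("aut", "cre"))
Description: Detects paralog pairs originating from the teleost-specific
    whole-genome duplication (TSGD) in a two-lineage genome panel and
    classifies lineage-specific paralog retention (LSPs): duplicate pairs
    kept in every genome of one superorder while the other superorder keeps
    a single copy. Provides Smith-Waterman protein similarity search with
    Karlin-Altschul E-values, reciprocal-best-hit orthology, a filtering
    cascade (isoform/chimera exclusion, different-chromosome criterion,
    pre-duplication outgroup singleton test, per-species copy-number
    scoring), distance-tree and synteny verification of candidate LSPs,
    chromosome-distribution statistics with permutation tests, GO-slim
    hypergeometric enrichment, and a fully synthetic post-WGD genome-panel
    simulator with ground-truth retention labels so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
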