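Package: lymphsig
Title: Digital Multiplexed Gene Expression Signatures for CLL Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for NanoString nCounter digital multiplexed
    gene-expression (DMGE) count data from B-cell chronic lymphoproliferative
    disorders. Implements control-based background correction, geNorm
    reference-gene stability ranking, geometric-mean housekeeping
    normalization, a fold-change/floor/t-test differential-expression filter
    cascade with gene-list set algebra and a coefficient-of-variation
    homogeneity filter, derivation of diagnostic and IgVH mutation-status
    gene signatures for chronic lymphocytic leukemia, ratio-based markers
    (kappa/lambda light-chain clonality, LDOC1/ADAM29 trichotomy,
    LPL/ADAM29 surrogate), PCA embedding and hierarchical-clustering
    classification, and a seeded synthetic-cohort generator that emulates
    the statistical structure of the platform for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
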