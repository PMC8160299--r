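Package: gpcrome
Title: GPCRome Percentile Profiling and Consensus Signatures for Microglia
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to profile G-protein-coupled receptor (GPCR) and
    G-protein-signaling gene expression against the whole transcriptome by
    percentile rank, classify genes into expression tiers, derive
    cross-dataset consensus core gene sets with a white-matter rescue rule,
    run paired regional differential analysis with exact nonparametric
    tests, and summarize single-cell cluster contrasts. Includes
    synthetic-data generators with planted ground truth so every pipeline
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
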