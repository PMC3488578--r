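Package: cghcohort
Title: Cohort Copy-Number Analysis for BAC Array-CGH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for BAC-clone array comparative genomic
    hybridization (array-CGH) cohorts: block-wise normalization of spot
    log2 ratios against self-self hybridization statistics, exact Bayesian
    changepoint segmentation of genome-ordered clone profiles under a
    product-partition model with ternary gain/neutral/loss calling,
    cohort-level imbalance-region detection at a frequency threshold,
    cross-cohort common-region intersection, stratified signed-frequency
    comparison between clinical groups, hypergeometric candidate-gene
    enrichment with copy-number/expression concordance filtering, and
    scoring rules for qPCR, CISH and IHC validation assays. Includes a
    synthetic-data generator with planted copy-number states so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
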