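Package: thssdiff
Title: Differential Tn5 Hypersensitive Site Analysis with Motif and
    Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of ATAC-seq chromatin accessibility and
    RNA-seq expression between two conditions across differentiation
    stages. Implements Tn5 cut-site offsetting and fragment size-class
    filtering, MA-based between-sample normalization of peak fragment
    counts with an exact binomial per-peak test and compound selection
    criteria, position-weight-matrix motif scanning in peak summit windows
    with exact score p-values and per-motif Fisher enrichment
    contingencies, floored log2 expression-ratio matrices, gene-set
    overlap tests, peak-to-gene proximity association, and enhancer
    overlap accounting. Ships a seeded synthetic-data generator that
    emulates the assumed data structure (two conditions, four stages, two
    replicates) with planted ground truth for end-to-end recovery tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
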