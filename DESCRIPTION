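Package: hicstates
Title: TAD and Enhancer-Promoter Loop Analysis of Hi-C Maps Across Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative 3D-epigenome analysis of binned Hi-C
    contact matrices from multiple cell lines (for example, one normal and two
    cancer lines). Provides iterative-correction (ICE) matrix balancing,
    resolution coarsening, diamond-statistic (TopDom-style) TAD calling,
    cross-cell-line TAD matching and classification, histone-mark TAD-state
    annotation with empirical random-TAD nulls, distance-stratified binomial
    chromatin-loop significance with Benjamini-Hochberg control, sequential
    promoter/enhancer/insulator anchor annotation, cell-type-specific
    enhancer-promoter loop classification, differential loop and expression
    tests, and a fully seeded synthetic-data generator that plants TADs,
    loops, peaks, bias and expression effects with recorded ground truth so
    every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
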