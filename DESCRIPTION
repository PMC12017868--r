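Package: periLoop
Title: Calibrated ChIP-Seq and Micro-C Analytics for Pericentromeric
    Cohesin Loops
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studying cohesin- and
    Scc2-dependent chromosome folding in budding yeast.  Implements
    spike-in calibrated ChIP-seq quantification (occupancy ratios,
    normalization factors, normalized fold-enrichment tracks, threshold
    peak calling), site-level statistics (quartile grouping, ratio
    analysis against a control median, aggregate profiles, centromere
    distance annotation), cis contact-map analytics (iterative matrix
    balancing, per-arm expected models, contact-versus-distance decay
    curves, insulation scores, donut-background loop calling, aggregate
    peak analysis, loop classification), gene-orientation barrier
    analysis, and a synthetic dual-genome data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
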