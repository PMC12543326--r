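Package: enhancerstate
Title: Consensus Peaks, Differential Histone-Mark Binding and Enhancer-State
    Classification for ChIP-seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replicate-consensus peakset construction, summit-centred window
    testing of histone-mark ChIP-seq counts with trimmed-mean-of-M-values
    normalisation and a conditional negative-binomial exact test,
    Benjamini-Hochberg FDR calling of differentially bound regions,
    six-way poised/active enhancer gain/loss classification from
    H3K4me1/H3K27ac evidence, promoter-window gene annotation, and a
    chi-squared gene-set overlap test for bivalency resolution. Includes a
    synthetic-data generator that plants a full enhancer/promoter
    architecture with known differential states so the whole pipeline can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
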