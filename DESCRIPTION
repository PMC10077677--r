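Package: irekit
Title: Comparative Analysis of Injury-Responsive Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification and cross-species comparison of
    injury-responsive enhancers (IREs) from histone-mark ChIP-seq region
    counts. Provides differential enhancer calling with a negative-binomial
    exact-style test, IUPAC degenerate motif scanning with per-kilobase
    frequency statistics for AP-1 and ETS transcription factor families,
    enhancer-state classification from H3K27ac/H3K27me3 signal matrices,
    TPM quantification and simplified differential expression, single-cell
    based cell-type assignment of induced genes, orthologous enhancer
    mapping by affine-gap global alignment within 100 kb of orthologous
    gene TSSs, shared versus species-specific enhancer classification,
    reporter-assay and qPCR arithmetic, and a two-species synthetic data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Matrix,
    Rcpp,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
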