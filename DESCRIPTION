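Package: ctvtsig
Title: Transcriptomic and Methylation Signatures of Transmissible Tumor Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for serial-biopsy studies of regressing canine
    transmissible venereal tumors (CTVT). Provides negative-binomial
    generalized linear model differential expression over a paired multi-dog
    design (median-of-ratios normalization, low-expression filtering,
    trend-shrunken method-of-moments dispersions, Wald contrasts,
    Benjamini-Hochberg adjustment, and a regressive-versus-non-regressive
    interaction test), temporal classification of significant genes into
    early, late, and progressive classes, core-regression-signature set
    algebra, host-versus-tumor transcript-origin assignment from
    somatic-variant allele counts, qPCR tumor-burden quantification via
    standard curves, and feature-resolved meta-gene methylation profiling
    (seven ordered gene features by twenty bins). A synthetic-data generator
    emulating the paired study design with planted ground truth makes every
    stage verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
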