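Package: genetier
Title: Tiered Gene-Model Consolidation, Stage-Specific Expression and
    Genome Summary Statistics for Fungal Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consolidates gene models from multiple predictors (homology-based,
    transcript-based and ab initio sources) with tiered precedence rules based
    on predictor score, span overlap and coding-sequence coverage; quantifies
    expression as RPKM with quantile normalization and log2 transformation;
    classifies genes into a four-condition expressed/not-expressed Venn
    partition with stage- and tissue-specificity flags; computes assembly and
    gene-set summary statistics (N50/L50, windowed GC content and gene
    density, exon/intron means); and provides seeded simulators for genomes,
    multi-source gene-model sets with known consolidation ground truth, and
    negative-binomial count matrices with planted stage-specific genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
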