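Package: crosspeak
Title: Integration of Chromatin Accessibility and Gene Expression Archetypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of ATAC-seq peak accessibility and RNA-seq gene
    expression across a six-condition lens epithelial explant design:
    median-of-ratios normalization, significance filtering of differential
    features, K-means archetype clustering, ChIPseeker-style genomic feature
    annotation with nearest-TSS assignment, peak-to-gene matching,
    expression/accessibility correlation, fixed-margin permutation tests for
    cluster cross-tables, direction-concordance tables with a Fisher exact
    test, TSS metaprofiles by expression quintile, and binned PWM motif
    enrichment.  A synthetic-data generator with planted cluster archetypes,
    associations and correlations provides a ground-truth test surface so no
    external download is required.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
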