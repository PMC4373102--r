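Package: dmrscape
Title: Differentially Methylated Region Landscapes from MeDIP-Chip Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects between-tumor differentially methylated regions (DMRs)
    from probe-level methylation-enrichment (MeDIP-chip) scores using a
    variance statistic with a CpG-density-matched permutation null, derives
    stable tumor methylation subgroups by bootstrap consensus clustering,
    partitions subgroup-specific DMRs into three archetypal methylation
    patterns, annotates DMRs against CpG islands, chromatin-state
    segmentations, regulatory-factor ChIP-seq peaks, repeats and conserved
    elements, integrates gene expression through resampling-based empirical
    correlation thresholds, and classifies a HOXA-like epigenetic switch with
    survival stratification. A synthetic-cohort generator with known ground
    truth emulates the statistical structure the pipeline assumes, so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Clustering, Microarray
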