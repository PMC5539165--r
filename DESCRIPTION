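Package: macEnhancers
Title: Macrophage Enhancer Landscape Dynamics from ChIP-seq, GRO-seq and
    Time-Course RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for studying how loss of the circadian
    transcription factor Bmal1 (Arntl) reshapes the TLR4-responsive enhancer
    landscape of macrophages. Provides genomic-interval peak hygiene and
    transcription-factor co-occupancy analysis (score filtering, blacklist
    subtraction, condition pooling, Venn summaries), fuzzy c-means clustering
    of KLA time-course transcriptomes with membership thresholds, H3K27ac
    tag-density metaprofiles and heatmap matrices with K-means row grouping,
    fold-change calling of KLA-activated enhancers, and a GRO-seq eRNA
    de-repression filter cascade. A seeded synthetic-data generator plants
    ground truth (bound factors, activated enhancers, de-repressed eRNAs,
    temporal expression templates) so that every stage can be scored for
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'macEnhancers-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'clustering.R'
    'peakset.R'
    'simulate.R'
    'tag-density.R'
    'enhancer-dynamics.R'
    'erna.R'
    'pipeline.R'
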