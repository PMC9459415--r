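Package: polpause
Title: Promoter-Proximal Pol II Pausing and Chromatin Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for nascent transcription
    (tNET-seq) and chromatin accessibility (ATAC-seq) data in aging tissue.
    Records RNA polymerase II density at nucleotide resolution from the 5'
    ends of stranded reads, computes promoter-proximal pausing indices over
    strand-aware promoter and gene-body windows, identifies active enhancers
    by combining H3K27ac, H3K4me3 and ATAC consensus peak logic, quantifies
    regions into count matrices with negative-binomial Wald and likelihood
    ratio tests, clusters expression trajectories by divisive hierarchical
    clustering on Kendall distances, and builds metagene profile matrices.
    Ships a synthetic-data generator with closed-form ground truth so every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    DESeq2,
    optparse
Config/testthat/edition: 3
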