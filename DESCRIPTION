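Package: regmodes
Title: Promoter Activity Scoring and Regulatory-Mode Classification from
    Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of promoter chromatin state, nascent
    transcription, steady-state mRNA and relative protein abundance across two
    cellular states. Scores promoter activity from histone-modification
    ChIP-seq tags with a cumulative RPKM (cRPKM) statistic, classifies
    promoters into four activity classes, quantifies GRO-seq/RNA-seq signal
    and an inferred mRNA stability ratio, and assigns each gene one of 27
    three-axis regulatory combinations collapsed into transcriptional,
    post-transcriptional, ambiguous and no-protein-change modes. Includes
    genomic-interval enrichment statistics (Jaccard, projection and
    relative-distance tests), rank-sum comparisons, a fully parameterised
    synthetic-data generator with ground truth, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
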