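Package: cutacProfiler
Title: Spike-Calibrated Chromatin Profiling at Promoters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of antibody-tethered tagmentation
    (CUT&Tag/CUTAC) fragment data around gene promoters: spike-in and
    normalized-count calibration of per-base coverage tracks,
    TSS-anchored binned coverage matrices with k-means promoter
    clustering, nearest-upstream promoter spacing with divergent/tandem
    orientation calls, decile moving-median statistics relating
    accessibility to inter-promoter distance, upstream torsion summaries
    with an SD-based outlier filter, expression-quintile stratification,
    and per-bin treatment-versus-control fold-change profiles. Includes
    a synthetic fragment generator with plantable effects so the whole
    pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    optparse
biocViews: Epigenetics, ATACSeq, Coverage, Transcription, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
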