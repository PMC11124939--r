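Package: bulkscan
Title: Bulked Segregant Analysis Sequencing with RNA-Seq Co-Analysis for
    Candidate Gene Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for localizing trait genes from pooled sequencing of
    phenotypically extreme bulks in biparental populations. Simulates F2
    populations with an ordinal phenotype under a major-gene model, builds
    extreme bulks and pooled read counts, computes delta SNP-index and
    Euclidean-distance association statistics with distance-weighted
    smoothing, simulation-based confidence thresholds and median + 3SD
    thresholds, calls and intersects candidate regions, refines them by
    marker co-segregation, and intersects region genes with differentially
    expressed genes to produce a ranked candidate list.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
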