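Package: spliceGaps
Title: Splice-Junction Detection, Classification and Exon-Intron Coverage
    Profiling from Spliced Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects splicing events as gaps in region-restricted spliced
    read alignments (SAM/BAM), aggregates identical gaps into read-supported
    splice junctions, classifies them against a single canonical transcript
    model (canonical, alternative acceptor/donor, skipped exon, added exon),
    groups events into loci, and profiles per-exon/per-intron aligned-base
    coverage by condition. Includes a seeded spliced paired-end read
    simulator with fragment-length and 3'-bias models that emits SAM plus an
    analytic ground-truth set, used to validate the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
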