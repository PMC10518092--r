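Package: fuseval
Title: Validation of RNA-Seq Fusion Transcripts in Matched Whole-Genome
    Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates gene-fusion transcripts detected in RNA-Seq against
    matched whole-genome sequencing (WGS) alignments. Fusion-junction
    coordinates define padded search regions for each fusion partner; read
    pairs linking the two regions are extracted from an indexed BAM file and
    filtered (PCR/optical duplicates, multimapping reads, short
    intrachromosomal fragments). Around surviving discordant pairs,
    soft-clipped read ends are collected, quality-filtered, and locally
    realigned into the partner region to identify genomic breakpoints with
    per-read support counts. A bundled paired-end WGS simulator generates
    reference genomes, fused alleles, and aligned read sets with truth
    manifests so that every pipeline stage can be tested hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
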