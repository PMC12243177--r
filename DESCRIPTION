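Package: tiscaller
Title: Transgene Insertion Site Detection from Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transgene (T-DNA) insertion sites in a host genome from
    short-read sequencing alignments (RNA-seq, ChIP-seq input, WGS). Soft-clipped
    reads are mined from SAM/BAM files, their clipped segments are aligned to a
    supplied T-DNA/vector sequence with border-distance-dependent filters, and
    chimeric junctions are reconstructed, merged across biological replicates,
    and scored with a five-category weighted evidence model. Calls are
    blacklist-filtered, gene-annotated, and exported as TSV/BED/bedGraph.
    Includes a read simulator that plants insertions into a synthetic genome and
    emits truth-derived alignments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
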