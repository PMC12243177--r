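#' @useDynLib tiscaller, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Reverse complement of a DNA string
#'
#' Plain character interface used throughout the simulator and junction code;
#' non-ACGT characters map to N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a CIGAR string into operations
#'
#' @param cigar a single CIGAR string.
#' @return data.frame with columns `len` (integer) and `op` (character), in
#'   order; NULL when the CIGAR is malformed.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) return(NULL)
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L) return(NULL)
  # reject any stray characters
  if (nchar(cigar) != sum(nchar(lens)) + length(ops)) return(NULL)
  data.frame(len = as.integer(lens), op = ops, stringsAsFactors = FALSE)
}

# query-consuming and reference-consuming CIGAR ops
.Q_OPS <- c("M", "I", "S", "=", "X")
.R_OPS <- c("M", "D", "N", "=", "X")
.ALN_OPS <- c("M", "=", "X")

#' Default minimum genome-aligned fraction for a given read length
#'
#' The minimum fraction of a read that must align to the genome before its
#' soft clip is considered: 0.67 for reads under 100 bp, 0.50 for 100-124 bp,
#' 0.33 for 125-151 bp (and longer). Shorter reads need a larger anchored
#' fraction because their clips are short and noisy.
#'
#' @param read_len integer vector of read lengths (bp).
#' @return numeric vector of fractions.
#' @export
auto_min_match_fraction <- function(read_len) {
  ifelse(read_len < 100, 0.67, ifelse(read_len < 125, 0.50, 0.33))
}
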