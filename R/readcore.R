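#' Read alignment records from SAM/BAM
#'
#' Loads the fields needed for soft-clip mining from a SAM or BAM file.
#' SAM input is converted to BAM in a temporary directory first. All records
#' are returned, including unmapped mates (needed by the optional
#' discordant-pair stage).
#'
#' @param path path to a SAM or BAM file.
#' @param replicate_id label for the biological replicate this file belongs to.
#' @return data.frame with one row per alignment record: `read_id`,
#'   `replicate_id`, `chrom`, `pos`, `strand`, `cigar`, `seq`, `qual`, `mapq`,
#'   `flag`, `is_paired`, `is_proper_pair`, `is_unmapped`, `mate_unmapped`,
#'   `is_first_mate`, `mate_chrom`, `mate_pos`.
#' @export
read_alignments <- function(path, replicate_id = basename(path)) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "seq", "qual", "mrnm", "mpos"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  if (length(flag) == 0L) replicate_id <- character(0)
  data.frame(
    read_id = b$qname,
    replicate_id = replicate_id,
    chrom = as.character(b$rname),
    pos = b$pos,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    mapq = b$mapq,
    flag = flag,
    is_paired = bitwAnd(flag, 1L) > 0L,
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    is_unmapped = bitwAnd(flag, 4L) > 0L,
    mate_unmapped = bitwAnd(flag, 8L) > 0L,
    is_first_mate = bitwAnd(flag, 64L) > 0L,
    mate_chrom = as.character(b$mrnm),
    mate_pos = b$mpos,
    stringsAsFactors = FALSE)
}

#' Extract soft-clipped segments from alignment records
#'
#' One record is emitted per qualifying `S` operation, so a read clipped at
#' both ends yields two records. Hard clips never qualify. Reads whose
#' genome-aligned length (`M`/`=`/`X` query bases) falls below
#' `r_min_match_fraction` of the read length are discarded, as are clips
#' shorter than `min_clip`. Records with a malformed CIGAR or missing sequence
#' are skipped with a warning rather than aborting the stream.
#'
#' @param alignments data.frame as returned by [read_alignments()].
#' @param r_min_match_fraction minimum fraction of the read that must be
#'   genome-aligned; `NULL` selects per read by length via
#'   [auto_min_match_fraction()].
#' @param min_clip minimum clip length (bp) for a record to be emitted.
#' @param min_mapq minimum mapping quality of the genomic alignment
#'   (0 for RNA-seq mode, 30 for WGS mode).
#' @return data.frame of soft-clip records: `read_id`, `replicate_id`,
#'   `chrom`, `aligned_start`, `aligned_end` (1-based closed genomic span),
#'   `clip_side` ("left"/"right"), `clip_seq`, `clip_quals`, `clip_len`,
#'   `read_len`, `genome_match_len`, `read_seq`, `genome_seq`.
#' @export
extract_soft_clips <- function(alignments, r_min_match_fraction = NULL,
                               min_clip = 1L, min_mapq = 0L) {
  stopifnot(is.null(r_min_match_fraction) ||
            (r_min_match_fraction > 0 && r_min_match_fraction <= 1))
  a <- alignments[!alignments$is_unmapped & !is.na(alignments$cigar) &
                  alignments$cigar != "*" & alignments$mapq >= min_mapq, ,
                  drop = FALSE]
  # fast pre-filter: only CIGARs containing S can yield records
  a <- a[grepl("S", a$cigar, fixed = TRUE), , drop = FALSE]
  out <- vector("list", nrow(a))
  n_bad <- 0L
  for (i in seq_len(nrow(a))) {
    rec <- extract_clips_one(a$read_id[i], a$replicate_id[i], a$chrom[i],
                             a$pos[i], a$cigar[i], a$seq[i], a$qual[i],
                             r_min_match_fraction, min_clip)
    if (is.null(rec)) next
    if (identical(rec, "malformed")) { n_bad <- n_bad + 1L; next }
    out[[i]] <- rec
  }
  if (n_bad > 0L)
    warning(n_bad, " record(s) skipped (malformed CIGAR or missing sequence)")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_softclip_frame())
  do.call(rbind, out)
}

empty_softclip_frame <- function() {
  data.frame(read_id = character(), replicate_id = character(),
             chrom = character(), aligned_start = integer(),
             aligned_end = integer(), clip_side = character(),
             clip_seq = character(), clip_quals = character(),
             clip_len = integer(), read_len = integer(),
             genome_match_len = integer(), read_seq = character(),
             genome_seq = character(), stringsAsFactors = FALSE)
}

# Per-record clip extraction; returns NULL (no record), "malformed", or a
# one-or-two-row data.frame.
extract_clips_one <- function(read_id, replicate_id, chrom, pos, cigar,
                              seq, qual, r, min_clip) {
  ops <- parse_cigar(cigar)
  if (is.null(ops)) return("malformed")
  if (is.na(seq) || seq == "*" || !nzchar(seq)) return("malformed")
  q_consume <- ops$op %in% .Q_OPS
  read_len <- sum(ops$len[q_consume])
  if (read_len != nchar(seq)) return("malformed")
  genome_match_len <- sum(ops$len[ops$op %in% .ALN_OPS])
  ref_len <- sum(ops$len[ops$op %in% .R_OPS])
  r_eff <- if (is.null(r)) auto_min_match_fraction(read_len) else r
  if (genome_match_len < r_eff * read_len) return(NULL)
  aligned_start <- pos
  aligned_end <- pos + ref_len - 1L
  # soft clips can only sit at the query ends (ignoring flanking H)
  s_idx <- which(ops$op == "S")
  if (length(s_idx) == 0L) return(NULL)
  # query offsets of each op
  q_end <- cumsum(ifelse(q_consume, ops$len, 0L))
  q_start <- q_end - ifelse(q_consume, ops$len, 0L) + 1L
  inner <- ops$op[!ops$op %in% c("S", "H")]
  rows <- list()
  for (k in s_idx) {
    side <- if (all(ops$op[seq_len(k - 1)] %in% "H")) "left" else "right"
    clip_len <- ops$len[k]
    if (clip_len < min_clip) next
    cs <- substr(seq, q_start[k], q_end[k])
    cq <- substr(qual, q_start[k], q_end[k])
    # genomic (non-clip) query portion
    gstart <- if (side == "left") q_end[k] + 1L else 1L
    gend <- if (side == "left") read_len else q_start[k] - 1L
    # trim the opposite clip off the genomic portion when both ends clipped
    other <- setdiff(s_idx, k)
    if (length(other) == 1L) {
      if (side == "left") gend <- q_start[other] - 1L else gstart <- q_end[other] + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = read_id, replicate_id = replicate_id, chrom = chrom,
      aligned_start = aligned_start, aligned_end = aligned_end,
      clip_side = side, clip_seq = cs, clip_quals = cq,
      clip_len = clip_len, read_len = read_len,
      genome_match_len = genome_match_len, read_seq = seq,
      genome_seq = substr(seq, gstart, gend), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Remove PCR duplicates among soft-clip records
#'
#' Within each replicate, records identical in genomic span, clip side and
#' full read sequence are collapsed to one. The key uses the full read
#' sequence rather than the clip alone so that reads with distinct
#' genome/T-DNA split ratios survive (they are Group-1 evidence downstream).
#' The result is sorted canonically, making the operation order-independent
#' and idempotent.
#'
#' @param records soft-clip records from [extract_soft_clips()].
#' @return deduplicated records in canonical order.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$replicate_id, records$chrom, records$aligned_start,
             records$aligned_end, records$clip_side, records$read_seq,
             records$read_id)
  records <- records[o, , drop = FALSE]
  key <- paste(records$replicate_id, records$chrom, records$aligned_start,
               records$aligned_end, records$clip_side, records$read_seq,
               sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate cleaved reads from soft-clip records
#'
#' A cleaved read is the reference-unaligned (clipped) portion of a
#' soft-clipped read, carried forward for alignment against the T-DNA.
#' Records are emitted when the clip is at least `l1` bases long and the
#' N-fraction of the genome-aligned portion of the read is below
#' `polyN_max` (records at or above the cutoff are excluded).
#'
#' @param records deduplicated soft-clip records.
#' @param l1 minimum clip length in bp (inclusive).
#' @param polyN_max N-fraction of the genomic portion at which a record is
#'   excluded.
#' @return the qualifying records with an added `cleave_id` column (unique
#'   FASTQ-ready identifier); clipped qualities are preserved.
#' @export
make_cleaved_reads <- function(records, l1 = 18L, polyN_max = 0.8) {
  if (nrow(records) == 0L) {
    records$cleave_id <- character(0)
    return(records)
  }
  nfrac <- vapply(records$genome_seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return(1)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / n
  }, numeric(1), USE.NAMES = FALSE)
  keep <- records$clip_len >= l1 & nfrac < polyN_max
  out <- records[keep, , drop = FALSE]
  out$cleave_id <- if (nrow(out) == 0L) character(0) else
    paste0(out$read_id, "/", substr(out$clip_side, 1, 1), ":",
           out$chrom, ":", out$aligned_start)
  rownames(out) <- NULL
  out
}

#' Write cleaved reads as FASTQ
#'
#' @param cleaved cleaved reads from [make_cleaved_reads()].
#' @param path output FASTQ path (4-line records, Phred+33 qualities).
#' @return `path`, invisibly.
#' @export
write_cleaved_fastq <- function(cleaved, path) {
  lines <- character(0)
  if (nrow(cleaved) > 0L)
    lines <- as.vector(rbind(paste0("@", cleaved$cleave_id),
                             cleaved$clip_seq, "+", cleaved$clip_quals))
  writeLines(lines, path)
  invisible(path)
}

#' Collect discordant read-pair candidates
#'
#' Optional stage (off by default in the pipeline): finds pairs where exactly
#' one mate has a confident genomic alignment (mapped, `mapq >= min_mapq`)
#' and the other is unmapped or not properly paired. The non-genomic mate's
#' sequence is retained for T-DNA alignment downstream (Group-5 evidence).
#'
#' @param alignments data.frame from [read_alignments()].
#' @param min_mapq minimum mapping quality of the genomic (anchor) mate.
#' @return data.frame with `pair_id`, `replicate_id`, `chrom`, `anchor_start`,
#'   `anchor_end`, `anchor_strand`, `other_seq`, `other_quals`. Single-end
#'   input yields an empty frame with a message.
#' @export
extract_discordant_candidates <- function(alignments, min_mapq = 30L) {
  empty <- data.frame(pair_id = character(), replicate_id = character(),
                      chrom = character(), anchor_start = integer(),
                      anchor_end = integer(), anchor_strand = character(),
                      other_seq = character(), other_quals = character(),
                      stringsAsFactors = FALSE)
  a <- alignments[alignments$is_paired, , drop = FALSE]
  if (nrow(a) == 0L) {
    message("no paired-end records: discordant-pair stage yields nothing")
    return(empty)
  }
  out <- list()
  for (pid in unique(a$read_id)) {
    mates <- a[a$read_id == pid, , drop = FALSE]
    if (nrow(mates) != 2L) next
    anchored <- !mates$is_unmapped & mates$mapq >= min_mapq
    cand <- which(anchored)
    if (length(cand) != 1L) next  # need exactly one confident genomic anchor
    other <- 3L - cand
    if (!(mates$is_unmapped[other] || !mates$is_proper_pair[other])) next
    ref_len <- {
      ops <- parse_cigar(mates$cigar[cand])
      if (is.null(ops)) next
      sum(ops$len[ops$op %in% .R_OPS])
    }
    out[[length(out) + 1L]] <- data.frame(
      pair_id = pid, replicate_id = mates$replicate_id[cand],
      chrom = mates$chrom[cand], anchor_start = mates$pos[cand],
      anchor_end = mates$pos[cand] + ref_len - 1L,
      anchor_strand = mates$strand[cand],
      other_seq = mates$seq[other], other_quals = mates$qual[other],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
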