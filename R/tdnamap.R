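#' Describe a T-DNA / vector construct
#'
#' @param construct_id construct name.
#' @param sequence DNA string of the construct.
#' @param left_border_pos,right_border_pos 1-based coordinates of the left
#'   and right border reference points; default to the construct ends.
#'   Explicit coordinates support vectors supplied as full plasmids.
#' @param internal_blacklist optional data.frame (`start`, `end`, 1-based
#'   closed) of intra-construct intervals to mask, e.g. endogenous gene
#'   fragments carried on the vector.
#' @return an object of class `tdna_construct`.
#' @export
tdna_construct <- function(construct_id, sequence,
                           left_border_pos = 1L,
                           right_border_pos = nchar(sequence),
                           internal_blacklist = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("construct sequence is empty")
  stopifnot(left_border_pos >= 1L, right_border_pos <= L,
            left_border_pos < right_border_pos)
  structure(list(construct_id = construct_id, sequence = sequence,
                 length = L,
                 left_border_pos = as.integer(left_border_pos),
                 right_border_pos = as.integer(right_border_pos),
                 internal_blacklist = internal_blacklist),
            class = "tdna_construct")
}

#' Read T-DNA constructs from FASTA
#'
#' Multi-record FASTA is allowed; each record becomes one construct with
#' borders at its ends. An optional metadata TSV (columns `construct_id`,
#' `lb_pos`, `rb_pos`, and optionally `bl_start`/`bl_end` rows for internal
#' blacklist intervals) overrides border positions.
#'
#' @param fasta path to the construct FASTA.
#' @param meta optional path to the metadata TSV.
#' @return named list of [tdna_construct()] objects.
#' @export
read_tdna_fasta <- function(fasta, meta = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in T-DNA FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  md <- if (!is.null(meta)) utils::read.delim(meta, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_along(seqs)) {
    lb <- 1L; rb <- Biostrings::width(seqs)[i]; bl <- NULL
    if (!is.null(md) && ids[i] %in% md$construct_id) {
      row <- md[md$construct_id == ids[i], , drop = FALSE][1L, ]
      if (!is.na(row$lb_pos)) lb <- as.integer(row$lb_pos)
      if (!is.na(row$rb_pos)) rb <- as.integer(row$rb_pos)
      if (all(c("bl_start", "bl_end") %in% names(md))) {
        rows <- md[md$construct_id == ids[i] & !is.na(md$bl_start), ,
                   drop = FALSE]
        if (nrow(rows) > 0L)
          bl <- data.frame(start = rows$bl_start, end = rows$bl_end)
      }
    }
    out[[ids[i]]] <- tdna_construct(ids[i], as.character(seqs[[i]]), lb, rb, bl)
  }
  out
}

#' Distance from a construct span to the nearest border
#'
#' Zero when the span covers or abuts a border reference point.
#'
#' @param t_start,t_end 1-based closed span on the construct.
#' @param construct a [tdna_construct()].
#' @return distance in bp.
#' @export
border_distance <- function(t_start, t_end, construct) {
  if (any(t_start < 1L) || any(t_end > construct$length) || any(t_start > t_end))
    stop("span outside construct [1, ", construct$length, "]")
  dist_to <- function(p) ifelse(p >= t_start & p <= t_end, 0L,
                                pmin(abs(t_start - p), abs(t_end - p)))
  pmin(dist_to(construct$left_border_pos), dist_to(construct$right_border_pos))
}

#' Align one cleaved read to a T-DNA construct
#'
#' Both strands are searched. An end-to-end placement (the whole clip,
#' ungapped, at most `m` mismatches) is preferred; otherwise the best local
#' placement is returned: a contiguous ungapped sub-segment, starting and
#' ending on a match, with at most `m` mismatches. Best means maximal matched
#' length, ties broken by fewer mismatches, then smaller construct start,
#' then + strand. `NULL` when no placement reaches `l1` matched bases within
#' the mismatch budget.
#'
#' @param clip_seq clipped segment (reference orientation).
#' @param construct a [tdna_construct()].
#' @param m mismatch budget.
#' @param l1 minimum matched length (bp).
#' @return one-row data.frame (`construct_id`, `t_start`, `t_end`, `t_strand`,
#'   `mode`, `matched_len`, `mismatches`, `q_start`, `q_end`,
#'   `border_distance`) or `NULL`.
#' @export
align_clip_to_tdna <- function(clip_seq, construct, m = 1L, l1 = 18L) {
  if (construct$length == 0L) stop("construct sequence is empty")
  h <- .align_clip_cpp(toupper(clip_seq), construct$sequence,
                       as.integer(m), as.integer(l1))
  if (!h$found) return(NULL)
  data.frame(construct_id = construct$construct_id,
             t_start = h$t_start, t_end = h$t_end, t_strand = h$t_strand,
             mode = h$mode, matched_len = h$matched_len,
             mismatches = h$mismatches, q_start = h$q_start, q_end = h$q_end,
             border_distance = border_distance(h$t_start, h$t_end, construct),
             stringsAsFactors = FALSE)
}

#' Align all cleaved reads to the supplied construct(s)
#'
#' Each cleaved read is aligned to every construct; only the single global
#' best hit is kept (so one clip can never seed two insertion sites). Ties
#' between constructs keep the lexicographically first construct id, with a
#' message.
#'
#' @param cleaved cleaved reads from [make_cleaved_reads()].
#' @param constructs list of [tdna_construct()] objects.
#' @param m mismatch budget.
#' @param l1 minimum matched length (bp).
#' @return data.frame of hits joined to their source records (all cleaved
#'   columns plus the hit columns); reads without a hit are absent.
#' @export
align_clips <- function(cleaved, constructs, m = 1L, l1 = 18L) {
  if (inherits(constructs, "tdna_construct")) constructs <- list(constructs)
  cids <- vapply(constructs, `[[`, character(1), "construct_id")
  constructs <- constructs[order(cids)]
  out <- vector("list", nrow(cleaved))
  n_tie <- 0L
  for (i in seq_len(nrow(cleaved))) {
    best <- NULL
    for (cons in constructs) {
      h <- align_clip_to_tdna(cleaved$clip_seq[i], cons, m = m, l1 = l1)
      if (is.null(h)) next
      if (is.null(best)) { best <- h; next }
      cmp <- hit_rank(h) - hit_rank(best)
      better <- which(cmp != 0)
      if (length(better) > 0L && cmp[better[1]] < 0) best <- h
      else if (length(better) == 0L) n_tie <- n_tie + 1L  # keep first (lexicographic)
    }
    if (!is.null(best)) out[[i]] <- cbind(cleaved[i, , drop = FALSE], best)
  }
  if (n_tie > 0L) message(n_tie, " clip(s) aligned equally well to >1 construct; ",
                          "kept the lexicographically first")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# rank vector for cross-construct comparison (smaller is better per component,
# checked in order): end2end first, longer match, fewer mismatches, smaller
# t_start, + strand
hit_rank <- function(h) {
  c(ifelse(h$mode == "end2end", 0L, 1L), -h$matched_len, h$mismatches,
    h$t_start, ifelse(h$t_strand == "+", 0L, 1L))
}

#' Filter T-DNA hits by border distance, matched length and mismatches
#'
#' Insertion junctions arise predominantly near the construct borders, so
#' hits within `d` bp of a border pass with the mild length threshold `l1`,
#' while hits at or beyond `d` must satisfy the stricter `l2`. Hits with more
#' than `m` mismatches are discarded, as are hits overlapping the construct's
#' internal blacklist. Pure predicate: output is a subset of input in stable
#' order, and the operation is idempotent.
#'
#' @param hits data.frame of hits (from [align_clips()]), with
#'   `border_distance`, `matched_len`, `mismatches`, `t_start`, `t_end`.
#' @param constructs list of [tdna_construct()] (for internal blacklists);
#'   optional when no construct carries one.
#' @param d border-distance cutoff (bp); "close" means strictly `< d`.
#' @param l1 minimum matched length near a border (inclusive).
#' @param l2 minimum matched length away from borders (inclusive).
#' @param m mismatch budget (hits with `mismatches > m` are discarded).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, constructs = NULL, d = 200L, l1 = 18L,
                        l2 = 30L, m = 1L) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  min_len <- ifelse(hits$border_distance < d, l1, l2)
  keep <- hits$mismatches <= m & hits$matched_len >= min_len
  if (!is.null(constructs)) {
    if (inherits(constructs, "tdna_construct")) constructs <- list(constructs)
    for (cons in constructs) {
      bl <- cons$internal_blacklist
      if (is.null(bl) || nrow(bl) == 0L) next
      for (j in seq_len(nrow(bl))) {
        inside <- hits$construct_id == cons$construct_id &
          hits$t_start <= bl$end[j] & hits$t_end >= bl$start[j]
        keep <- keep & !inside
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
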