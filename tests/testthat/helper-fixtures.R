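# in-code fixtures shared across test files

# one alignment record shaped like read_alignments() output
make_aln <- function(read_id = "r1", chrom = "chr1", pos = 1000L,
                     cigar = "100M", seq = NULL, qual = NULL, flag = 0L,
                     mapq = 60L, replicate_id = "rep1",
                     mate_chrom = NA_character_, mate_pos = NA_integer_) {
  if (is.null(seq) && !is.na(cigar) && cigar != "*") {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    qlen <- sum(vapply(ops, function(o) {
      op <- substr(o, nchar(o), nchar(o))
      if (op %in% c("M", "I", "S", "=", "X")) as.integer(substr(o, 1, nchar(o) - 1L)) else 0L
    }, integer(1)))
    seq <- paste(rep_len(c("A", "C", "G", "T"), qlen), collapse = "")
  }
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(read_id = read_id, replicate_id = replicate_id, chrom = chrom,
             pos = pos,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             cigar = cigar, seq = seq, qual = qual, mapq = mapq, flag = flag,
             is_paired = bitwAnd(flag, 1L) > 0L,
             is_proper_pair = bitwAnd(flag, 2L) > 0L,
             is_unmapped = bitwAnd(flag, 4L) > 0L,
             mate_unmapped = bitwAnd(flag, 8L) > 0L,
             is_first_mate = bitwAnd(flag, 64L) > 0L,
             mate_chrom = mate_chrom, mate_pos = mate_pos,
             stringsAsFactors = FALSE)
}

# a T-DNA hit row as consumed by filter_hits()
make_hit <- function(matched_len, border_distance, mismatches = 0L,
                     t_start = 500L, construct_id = "c1", t_strand = "+",
                     mode = "local") {
  data.frame(construct_id = construct_id, t_start = t_start,
             t_end = t_start + matched_len - 1L, t_strand = t_strand,
             mode = mode, matched_len = matched_len, mismatches = mismatches,
             q_start = 1L, q_end = matched_len,
             border_distance = border_distance, stringsAsFactors = FALSE)
}

# a chimeric read row as consumed by build_candidates()
make_chim <- function(read_id, junction, genome_seg_len, tdna_seg_len,
                      full_seq, replicate_id = "rep1", chrom = "chr1",
                      config = "R", orientation = "+", construct_id = "c1",
                      t_junction = 1L) {
  data.frame(read_id = read_id, replicate_id = replicate_id, chrom = chrom,
             junction = as.integer(junction), config = config,
             orientation = orientation, construct_id = construct_id,
             t_junction = t_junction,
             genome_seg_len = as.integer(genome_seg_len),
             tdna_seg_len = as.integer(tdna_seg_len),
             full_seq = full_seq, stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Independent exhaustive scorer for ungapped clip-vs-construct alignment.
# Enumerates every placement on both strands: end-to-end (whole clip, <= m
# mismatches) and every local window (start/end on a match, <= m mismatches,
# length >= l1). Returns the best by (end2end, matched_len desc, mismatches
# asc, t_start asc, + strand) or NULL.
oracle_align <- function(clip, construct, m = 1L, l1 = 18L) {
  Tv <- strsplit(construct, "")[[1]]
  L <- length(Tv)
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") clip else tiscaller::revcomp(clip)
    qv <- strsplit(q, "")[[1]]
    n <- length(qv)
    # end-to-end placements
    if (n <= L && n >= l1) {
      for (off in 0:(L - n)) {
        mm <- sum(qv != Tv[off + seq_len(n)])
        if (mm <= m)
          cands[[length(cands) + 1L]] <- data.frame(
            e2e = 1L, len = n, mm = mm, t_start = off + 1L, t_end = off + n,
            strand = strand)
      }
    }
    # all local windows, per diagonal
    for (diag in (-(n - 1L)):(L - 1L)) {
      i_lo <- max(1L, 1L - diag)
      i_hi <- min(n, L - diag)
      W <- i_hi - i_lo + 1L
      if (W < l1) next
      mmv <- qv[i_lo:i_hi] != Tv[(i_lo:i_hi) + diag]
      cs <- c(0L, cumsum(mmv))
      best <- NULL
      for (s in seq_len(W)) {
        if (mmv[s]) next
        for (e in s:W) {
          if (mmv[e]) next
          len <- e - s + 1L
          if (len < l1) next
          mm <- cs[e + 1L] - cs[s]
          if (mm > m) break
          key <- c(-len, mm, i_lo + s - 1L + diag)
          if (is.null(best) || isTRUE(vector_less(key, best$key)))
            best <- list(key = key, s = s, e = e, len = len, mm = mm)
        }
      }
      if (!is.null(best))
        cands[[length(cands) + 1L]] <- data.frame(
          e2e = 0L, len = best$len, mm = best$mm,
          t_start = i_lo + best$s - 1L + diag,
          t_end = i_lo + best$e - 1L + diag, strand = strand)
    }
  }
  if (length(cands) == 0L) return(NULL)
  d <- do.call(rbind, cands)
  d <- d[order(-d$e2e, -d$len, d$mm, d$t_start, d$strand), , drop = FALSE]
  d[1L, , drop = FALSE]
}

vector_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# small simulated dataset reused by pipeline tests; built once per test run
sim_fixture <- local({
  cache <- NULL
  function(dir = file.path(tempdir(), "tiscaller_sim")) {
    if (!is.null(cache)) return(cache)
    sim <- simulate_reference_and_tdna(seed = 7, genome_len = 100000L,
                                       n_expressed_intervals = 10L,
                                       tdna_len = 2000L,
                                       interval_width = 2000L)
    iv <- sim$intervals
    events <- data.frame(position = c(iv$start[2] + 1000L, iv$start[6] + 900L),
                         orientation = c("+", "-"),
                         left_truncation = c(0L, 50L),
                         right_truncation = c(30L, 0L))
    planted <- plant_insertions(sim$genome, sim$construct, events)
    reads <- simulate_reads(planted, iv, out_dir = dir, read_len = 150L,
                            depth = 40, error_rate = 0, n_replicates = 2L,
                            seed = 11L)
    cache <<- list(sim = sim, planted = planted, reads = reads)
    cache
  }
})
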