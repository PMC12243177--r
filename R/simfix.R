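#' Simulate a reference genome, expressed intervals and a T-DNA construct
#'
#' Builds a uniform-composition random genome, a set of non-overlapping
#' "expressed" intervals (the only regions reads are later sampled from,
#' emulating transcriptome coverage), and a random construct sequence with
#' borders at its ends. Byte-identical outputs for the same seed.
#'
#' @param seed RNG seed.
#' @param genome_len genome length in bp (>= 1000).
#' @param n_expressed_intervals number of expressed intervals.
#' @param tdna_len construct length in bp (>= 500).
#' @param interval_width width of each expressed interval in bp.
#' @param chrom chromosome name.
#' @return list with `genome` (named character, one chromosome), `intervals`
#'   (data.frame `chrom`, `start`, `end`, 1-based closed), and `construct`
#'   (a [tdna_construct()]).
#' @export
simulate_reference_and_tdna <- function(seed, genome_len = 100000L,
                                        n_expressed_intervals = 10L,
                                        tdna_len = 5000L,
                                        interval_width = 2000L,
                                        chrom = "chr1") {
  stopifnot(genome_len >= 1000L, tdna_len >= 500L)
  if (n_expressed_intervals * interval_width > genome_len)
    stop("expressed intervals cannot fit in the genome")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genome <- random_dna(genome_len)
  names(genome) <- chrom
  # place intervals by distributing the free space as random gaps
  free <- genome_len - n_expressed_intervals * interval_width
  cuts <- sort(sample.int(free + 1L, n_expressed_intervals, replace = TRUE)) - 1L
  starts <- cuts + (seq_len(n_expressed_intervals) - 1L) * interval_width + 1L
  intervals <- data.frame(chrom = chrom, start = as.integer(starts),
                          end = as.integer(starts + interval_width - 1L),
                          stringsAsFactors = FALSE)
  construct <- tdna_construct("construct1", random_dna(tdna_len))
  list(genome = genome, intervals = intervals, construct = construct)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Plant T-DNA insertions into a genome sequence
#'
#' Each event inserts the (optionally border-truncated, orientation-respecting)
#' construct between `position` and `position + 1` of the original sequence.
#' Truncation models the frequent loss of border sequence before integration.
#' The truth table records, per event, the two expected flank junctions in
#' original coordinates: R (reference-then-T-DNA) at `position`, L at
#' `position + 1`.
#'
#' @param genome named character vector of length 1 (one chromosome).
#' @param construct a [tdna_construct()].
#' @param events data.frame with `position` (1-based, strictly increasing),
#'   `orientation` ("+"/"-"), `left_truncation`, `right_truncation` (bp).
#' @return list with `mutated` (character sequence), `truth` (data.frame with
#'   per-event coordinates and per-flank junctions), and `blocks` (internal
#'   mutated-to-original coordinate map used by [simulate_reads()]).
#' @export
plant_insertions <- function(genome, construct, events) {
  chrom <- names(genome)[1]
  gseq <- unname(genome[1])
  glen <- nchar(gseq)
  if (nrow(events) == 0L) {
    return(list(mutated = stats::setNames(gseq, chrom),
                truth = empty_truth(),
                blocks = data.frame(type = "genome", m_start = 1L,
                                    m_end = glen, orig_start = 1L,
                                    event = NA_integer_,
                                    stringsAsFactors = FALSE)))
  }
  if (is.null(events$left_truncation)) events$left_truncation <- 0L
  if (is.null(events$right_truncation)) events$right_truncation <- 0L
  if (is.unsorted(events$position, strictly = TRUE))
    stop("events must be sorted by position and non-overlapping")
  stopifnot(all(events$position >= 1L), all(events$position < glen),
            all(events$left_truncation >= 0L), all(events$right_truncation >= 0L),
            all(events$left_truncation + events$right_truncation < construct$length))
  pieces <- character(0)
  blocks <- list()
  truth <- list()
  cursor <- 1L   # next original base to copy
  m_cursor <- 0L # mutated length so far
  for (i in seq_len(nrow(events))) {
    p <- events$position[i]
    ins <- substr(construct$sequence, 1L + events$left_truncation[i],
                  construct$length - events$right_truncation[i])
    if (events$orientation[i] == "-") ins <- revcomp(ins)
    gpart <- substr(gseq, cursor, p)
    pieces <- c(pieces, gpart, ins)
    blocks[[length(blocks) + 1L]] <- data.frame(
      type = "genome", m_start = m_cursor + 1L,
      m_end = m_cursor + nchar(gpart), orig_start = cursor,
      event = NA_integer_, stringsAsFactors = FALSE)
    m_cursor <- m_cursor + nchar(gpart)
    blocks[[length(blocks) + 1L]] <- data.frame(
      type = "construct", m_start = m_cursor + 1L,
      m_end = m_cursor + nchar(ins), orig_start = NA_integer_,
      event = i, stringsAsFactors = FALSE)
    m_cursor <- m_cursor + nchar(ins)
    truth[[i]] <- data.frame(
      event = i, chrom = chrom, position = p,
      orientation = events$orientation[i],
      left_truncation = events$left_truncation[i],
      right_truncation = events$right_truncation[i],
      junction_R = p, junction_L = p + 1L, stringsAsFactors = FALSE)
    cursor <- p + 1L
  }
  gpart <- substr(gseq, cursor, glen)
  pieces <- c(pieces, gpart)
  blocks[[length(blocks) + 1L]] <- data.frame(
    type = "genome", m_start = m_cursor + 1L, m_end = m_cursor + nchar(gpart),
    orig_start = cursor, event = NA_integer_, stringsAsFactors = FALSE)
  list(mutated = stats::setNames(paste(pieces, collapse = ""), chrom),
       truth = do.call(rbind, truth),
       blocks = do.call(rbind, blocks))
}

empty_truth <- function() {
  data.frame(event = integer(), chrom = character(), position = integer(),
             orientation = character(), left_truncation = integer(),
             right_truncation = integer(), junction_R = integer(),
             junction_L = integer(), stringsAsFactors = FALSE)
}

#' Flatten a truth table to per-flank junctions
#'
#' One R and one L junction per insertion event, for evaluation against
#' per-flank calls.
#'
#' @param truth truth table from [plant_insertions()].
#' @return data.frame with `chrom`, `junction`, `config`, `event`.
#' @export
truth_junctions <- function(truth) {
  if (nrow(truth) == 0L)
    return(data.frame(chrom = character(), junction = integer(),
                      config = character(), event = integer(),
                      stringsAsFactors = FALSE))
  rbind(data.frame(chrom = truth$chrom, junction = truth$junction_R,
                   config = "R", event = truth$event, stringsAsFactors = FALSE),
        data.frame(chrom = truth$chrom, junction = truth$junction_L,
                   config = "L", event = truth$event, stringsAsFactors = FALSE))
}

# map an original coordinate to mutated coordinates
map_to_mutated <- function(pos, blocks) {
  g <- blocks[blocks$type == "genome", , drop = FALSE]
  glen <- g$m_end - g$m_start + 1L
  for (i in seq_len(nrow(g))) {
    if (glen[i] > 0L && pos >= g$orig_start[i] && pos < g$orig_start[i] + glen[i])
      return(g$m_start[i] + (pos - g$orig_start[i]))
  }
  stop("position ", pos, " not in any genome block")
}

#' Simulate reads from the mutated genome and write truth-derived alignments
#'
#' Reads are sampled uniformly from the expressed intervals of the mutated
#' genome (both strands), with i.i.d. substitution errors. SAM records are
#' written against the ORIGINAL reference with soft-clip CIGARs computed from
#' the known breakpoints: a read overlapping a junction gets an `S` op exactly
#' covering its construct-derived portion; reads entirely inside the construct
#' are emitted unmapped. One RNG stream per replicate, seeded
#' `seed + replicate`. Deterministic given the seed.
#'
#' @param planted list from [plant_insertions()].
#' @param intervals expressed intervals in original coordinates (data.frame
#'   `chrom`, `start`, `end`).
#' @param out_dir output directory (created if needed).
#' @param read_len read length in bp (50-151).
#' @param layout "single" or "paired".
#' @param depth expected coverage over expressed intervals.
#' @param error_rate per-base substitution probability.
#' @param n_replicates number of biological replicates.
#' @param seed base RNG seed.
#' @param original_len length of the original reference (for the SAM header);
#'   inferred from the blocks when missing.
#' @return list with `sam` (per-replicate paths), `fastq` (per-replicate
#'   character vectors of paths), `truth_file`, `truth` (data.frame).
#' @export
simulate_reads <- function(planted, intervals, out_dir,
                           read_len = 150L, layout = c("single", "paired"),
                           depth = 30, error_rate = 0, n_replicates = 2L,
                           seed = 1L, original_len = NULL) {
  layout <- match.arg(layout)
  stopifnot(read_len >= 50L, read_len <= 151L, depth >= 0, error_rate >= 0,
            error_rate <= 1, n_replicates >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- names(planted$mutated)[1]
  mseq <- unname(planted$mutated[1])
  blocks <- planted$blocks
  if (is.null(original_len)) {
    g <- blocks[blocks$type == "genome", , drop = FALSE]
    original_len <- g$orig_start[nrow(g)] + (g$m_end[nrow(g)] - g$m_start[nrow(g)])
  }
  # expressed intervals in mutated coordinates (insertions inside an interval
  # stretch it)
  m_ivl <- data.frame(
    start = vapply(intervals$start, map_to_mutated, integer(1), blocks = blocks),
    end = vapply(intervals$end, map_to_mutated, integer(1), blocks = blocks))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  sam_paths <- character(n_replicates)
  fq_paths <- vector("list", n_replicates)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", chrom, "\tLN:", original_len))
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seed + rep_i)
    sam <- character(0)
    fq1 <- character(0); fq2 <- character(0)
    serial <- 0L
    for (iv in seq_len(nrow(m_ivl))) {
      ms <- m_ivl$start[iv]; me <- m_ivl$end[iv]
      span <- me - ms + 1L
      if (layout == "single") {
        if (span < read_len) next
        n_reads <- round(depth * span / read_len)
        if (n_reads < 1L) next
        starts <- ms + sample.int(span - read_len + 1L, n_reads, replace = TRUE) - 1L
        strands <- sample(c("+", "-"), n_reads, replace = TRUE)
        for (k in seq_len(n_reads)) {
          serial <- serial + 1L
          rid <- sprintf("rep%d_iv%d_%06d", rep_i, iv, serial)
          r <- render_read(rid, starts[k], read_len, strands[k], mseq, blocks,
                           chrom, error_rate, paired = 0L)
          sam <- c(sam, r$sam)
          fq1 <- c(fq1, r$fq)
        }
      } else {
        frag <- min(2L * read_len + 50L, span)
        if (frag < read_len) next
        n_pairs <- round(depth * span / (2 * read_len))
        if (n_pairs < 1L) next
        fstarts <- ms + sample.int(span - frag + 1L, n_pairs, replace = TRUE) - 1L
        for (k in seq_len(n_pairs)) {
          serial <- serial + 1L
          rid <- sprintf("rep%d_iv%d_%06d", rep_i, iv, serial)
          r1 <- render_read(rid, fstarts[k], read_len, "+", mseq, blocks,
                            chrom, error_rate, paired = 1L)
          r2 <- render_read(rid, fstarts[k] + frag - read_len, read_len, "-",
                            mseq, blocks, chrom, error_rate, paired = 2L)
          sam <- c(sam, r1$sam, r2$sam)
          fq1 <- c(fq1, r1$fq)
          fq2 <- c(fq2, r2$fq)
        }
      }
    }
    sam_paths[rep_i] <- file.path(out_dir, sprintf("rep%d.sam", rep_i))
    writeLines(c(header, sam), sam_paths[rep_i])
    if (layout == "single") {
      p <- file.path(out_dir, sprintf("rep%d.fastq", rep_i))
      writeLines(fq1, p)
      fq_paths[[rep_i]] <- p
    } else {
      p1 <- file.path(out_dir, sprintf("rep%d_1.fastq", rep_i))
      p2 <- file.path(out_dir, sprintf("rep%d_2.fastq", rep_i))
      writeLines(fq1, p1); writeLines(fq2, p2)
      fq_paths[[rep_i]] <- c(p1, p2)
    }
  }
  truth_file <- file.path(out_dir, "truth.tsv")
  utils::write.table(planted$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sam = sam_paths, fastq = fq_paths, truth_file = truth_file,
       truth = planted$truth)
}

# render one read sampled at mutated coordinate `start` into SAM + FASTQ lines
render_read <- function(rid, start, read_len, strand, mseq, blocks, chrom,
                        error_rate, paired = 0L) {
  end <- start + read_len - 1L
  seq_ref <- substr(mseq, start, end)  # reference-orientation bases
  if (error_rate > 0) seq_ref <- mutate_seq(seq_ref, error_rate)
  quals <- strrep("I", read_len)
  # decompose into blocks
  ov <- blocks[blocks$m_end >= start & blocks$m_start <= end, , drop = FALSE]
  flag <- 0L
  if (paired > 0L)
    flag <- flag + 1L + 2L + if (paired == 1L) 64L else 128L
  if (strand == "-") flag <- flag + 16L
  if (paired == 1L) flag <- flag + 32L  # mate of forward first mate is reverse
  if (nrow(ov) == 1L && ov$type == "genome") {
    pos <- ov$orig_start + (start - ov$m_start)
    cigar <- paste0(read_len, "M")
  } else if (nrow(ov) == 1L) {
    # wholly inside the construct: unmapped
    uflag <- 4L + if (paired > 0L) flag - bitwAnd(flag, 2L + 16L + 32L) else 0L
    sam <- paste(rid, uflag, "*", 0, 0, "*", "*", 0, 0, seq_ref, quals,
                 sep = "\t")
    return(list(sam = sam, fq = fastq_lines(rid, seq_ref, quals, strand, paired)))
  } else if (nrow(ov) == 2L && ov$type[1] == "genome") {
    gl <- ov$m_end[1] - start + 1L
    pos <- ov$orig_start[1] + (start - ov$m_start[1])
    cigar <- paste0(gl, "M", read_len - gl, "S")
  } else if (nrow(ov) == 2L && ov$type[1] == "construct") {
    cl <- ov$m_end[1] - start + 1L
    pos <- ov$orig_start[2]
    cigar <- paste0(cl, "S", read_len - cl, "M")
  } else {
    # spans three blocks (construct shorter than a read): emit unmapped
    sam <- paste(rid, 4L, "*", 0, 0, "*", "*", 0, 0, seq_ref, quals, sep = "\t")
    return(list(sam = sam, fq = fastq_lines(rid, seq_ref, quals, strand, paired)))
  }
  sam <- paste(rid, flag, chrom, pos, 60L, cigar, "*", 0, 0, seq_ref, quals,
               sep = "\t")
  list(sam = sam, fq = fastq_lines(rid, seq_ref, quals, strand, paired))
}

fastq_lines <- function(rid, seq_ref, quals, strand, paired) {
  s <- if (strand == "-") revcomp(seq_ref) else seq_ref
  tag <- if (paired == 0L) "" else paste0("/", paired)
  c(paste0("@", rid, tag), s, "+", quals)
}

mutate_seq <- function(s, rate) {
  bases <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based closed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start - 1L,
                   intervals$end)
  writeLines(lines, path)
  invisible(path)
}
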