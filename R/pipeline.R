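#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default. The
#' defaults mirror the method's printed settings: `l1 = 18`, `l2 = 30`,
#' `d = 200`, `m = 1`, weights 700/300/300/1/1, threshold 1000; `r = NULL`
#' selects the minimum genome-aligned fraction by read length
#' (see [auto_min_match_fraction()]). WGS mode differs from RNA-seq mode only
#' in the mapping-quality floor applied to the genomic alignments (30 vs 0).
#'
#' @param alignments character vector of SAM/BAM paths, one per replicate
#'   (names, when present, are replicate ids).
#' @param tdna_fasta path to the construct FASTA.
#' @param tdna_meta optional construct metadata TSV (see [read_tdna_fasta()]).
#' @param l1 mild minimum matched/clip length (bp).
#' @param l2 strict minimum matched length away from borders (bp).
#' @param d border-distance cutoff (bp).
#' @param m mismatch budget.
#' @param r minimum genome-aligned fraction of a read, or `NULL` for auto.
#' @param w candidate clustering window (bp).
#' @param weights a [scoring_weights()] object (carries the threshold).
#' @param polyN_max N-fraction cutoff on the genomic portion.
#' @param discordant enable the discordant-pair stage (Group 5).
#' @param D discordant anchor proximity window (bp).
#' @param min_mapq_discordant mapping-quality floor for discordant anchors.
#' @param blacklist optional BED path or `GRanges`.
#' @param gff optional GFF3 path or `GRanges`.
#' @param mode "rnaseq" or "wgs".
#' @param threads shard count; results are thread-count invariant.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alignments, tdna_fasta = NULL, tdna_meta = NULL,
                            l1 = 18L, l2 = 30L, d = 200L, m = 1L, r = NULL,
                            w = 10L, weights = scoring_weights(),
                            polyN_max = 0.8, discordant = FALSE, D = 1000L,
                            min_mapq_discordant = 30L, blacklist = NULL,
                            gff = NULL, mode = c("rnaseq", "wgs"),
                            threads = 1L) {
  mode <- match.arg(mode)
  stopifnot(l1 >= 1L, l2 >= l1, d >= 0L, m >= 0L, w >= 0L,
            polyN_max > 0, polyN_max <= 1, threads >= 1L)
  if (length(alignments) < 1L) stop("at least one replicate alignment file is required")
  if (is.null(names(alignments)))
    names(alignments) <- paste0("rep", seq_along(alignments))
  structure(list(alignments = alignments, tdna_fasta = tdna_fasta,
                 tdna_meta = tdna_meta, l1 = l1, l2 = l2, d = d, m = m, r = r,
                 w = w, weights = weights, polyN_max = polyN_max,
                 discordant = discordant, D = D,
                 min_mapq_discordant = min_mapq_discordant,
                 blacklist = blacklist, gff = gff, mode = mode,
                 threads = threads),
            class = "pipeline_config")
}

#' Run the full insertion-site detection pipeline
#'
#' Executes soft-clip extraction, deduplication, cleaved-read generation,
#' construct alignment and filtering, junction reconstruction, replicate
#' merging, evidence classification, scoring and calling. When `out_dir` is
#' given, writes `calls.tsv` (all candidates with status), `calls.bed`
#' (passing calls, BED6, score capped at 1000 for BED validity),
#' `coverage.bedGraph` (RPKM track) and `pipeline.log`. Output is
#' byte-identical regardless of `threads` (sharding is by replicate and
#' chromosome with a canonical merge).
#'
#' @param config a [pipeline_config()].
#' @param constructs optional pre-built list of [tdna_construct()] (overrides
#'   `config$tdna_fasta`).
#' @param out_dir optional output directory.
#' @return list with `calls` (annotated candidate data.frame), `chimeric`,
#'   `n_alignments`, and the output paths when written.
#' @export
run_pipeline <- function(config, constructs = NULL, out_dir = NULL) {
  if (is.null(constructs)) {
    if (is.null(config$tdna_fasta)) stop("a T-DNA FASTA (or constructs) is required")
    constructs <- read_tdna_fasta(config$tdna_fasta, config$tdna_meta)
  }
  if (inherits(constructs, "tdna_construct")) constructs <- list(constructs)
  min_mapq <- if (config$mode == "wgs") 30L else 0L
  log_lines <- c(sprintf("mode=%s replicates=%d constructs=%d threads=%d",
                         config$mode, length(config$alignments),
                         length(constructs), config$threads))
  chim_all <- list()
  disc_all <- list()
  n_aln <- 0L
  all_aln <- list()
  for (rep_id in names(config$alignments)) {
    aln <- read_alignments(config$alignments[[rep_id]], rep_id)
    all_aln[[rep_id]] <- aln
    n_aln <- n_aln + nrow(aln)
    # shard by chromosome; serial execution in canonical order keeps the
    # result identical for any shard/thread count
    chroms <- sort(unique(aln$chrom[!is.na(aln$chrom)]))
    shards <- if (config$threads > 1L) chroms else list(chroms)
    for (sh in shards) {
      sub <- aln[!is.na(aln$chrom) & aln$chrom %in% sh, , drop = FALSE]
      clips <- extract_soft_clips(sub, r_min_match_fraction = config$r,
                                  min_clip = config$l1, min_mapq = min_mapq)
      clips <- deduplicate(clips)
      cleaved <- make_cleaved_reads(clips, l1 = config$l1,
                                    polyN_max = config$polyN_max)
      if (nrow(cleaved) == 0L) next
      hits <- align_clips(cleaved, constructs, m = config$m, l1 = config$l1)
      hits <- filter_hits(hits, constructs, d = config$d, l1 = config$l1,
                          l2 = config$l2, m = config$m)
      if (is.null(hits) || nrow(hits) == 0L) next
      chim_all[[length(chim_all) + 1L]] <- reconstruct_junctions(hits)
    }
    if (config$discordant)
      disc_all[[rep_id]] <- extract_discordant_candidates(
        aln, min_mapq = config$min_mapq_discordant)
  }
  if (n_aln == 0L) warning("zero parsable alignments; report will be empty")
  chimeric <- if (length(chim_all) > 0L) do.call(rbind, chim_all)
              else reconstruct_junctions(NULL)
  # canonical order before clustering: thread-count invariance
  if (nrow(chimeric) > 0L) {
    chimeric <- chimeric[order(chimeric$chrom, chimeric$config,
                               chimeric$junction, chimeric$read_id,
                               chimeric$replicate_id), , drop = FALSE]
    rownames(chimeric) <- NULL
  }
  cands <- build_candidates(chimeric, w = config$w, weights = config$weights)
  if (config$discordant && length(disc_all) > 0L) {
    disc <- do.call(rbind, disc_all)
    cands <- attach_discordant_support(cands, disc, constructs, D = config$D,
                                       weights = config$weights, m = config$m,
                                       l1 = config$l1, l2 = config$l2,
                                       d = config$d)
  }
  calls <- call_tis(cands, threshold = config$weights$threshold,
                    blacklist = config$blacklist, annotation = config$gff)
  log_lines <- c(log_lines,
                 sprintf("alignments=%d chimeric=%d candidates=%d pass=%d",
                         n_aln, nrow(chimeric), nrow(calls),
                         sum(calls$status == "pass")))
  res <- list(calls = calls, chimeric = chimeric, n_alignments = n_aln)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res$tsv <- write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
    res$bed <- write_calls_bed(calls, file.path(out_dir, "calls.bed"))
    aln_mapped <- do.call(rbind, all_aln)
    aln_mapped <- aln_mapped[!aln_mapped$is_unmapped, , drop = FALSE]
    cov <- coverage_track(aln_mapped, bin_width = 100L)
    res$bedgraph <- write_bedgraph(cov, file.path(out_dir, "coverage.bedGraph"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    res$log <- file.path(out_dir, "pipeline.log")
  }
  res
}

#' Write the candidate report as TSV
#'
#' All candidates (pass and fail) with per-group supporter counts, score,
#' replicates and overlapping genes.
#'
#' @param calls data.frame from [call_tis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("chrom", "junction", "config", "orientation", "construct_id",
            "t_junction", "g1", "g2", "g3", "g4", "g5", "score",
            "replicates", "genes", "status")
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write passing calls as BED6
#'
#' 0-based half-open; name is `construct:config:orientation`; the BED score
#' column is capped at 1000 for format validity (the true score stays in the
#' TSV report); strand column carries the construct orientation.
#'
#' @param calls data.frame from [call_tis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  p <- calls[calls$status == "pass", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s:%s:%s\t%d\t%s",
                   p$chrom, p$junction - 1L, p$junction,
                   p$construct_id, p$config, p$orientation,
                   pmin(as.integer(p$score), 1000L), p$orientation)
  writeLines(lines, path)
  invisible(path)
}

#' RPKM coverage track from alignment records
#'
#' Bins each chromosome and computes
#' `reads_in_bin / ((bin_width/1000) * (total_mapped/1e6))` — reads per
#' kilobase per million mapped reads. A read is counted in the bin containing
#' its leftmost aligned base.
#'
#' @param alignments mapped alignment records ([read_alignments()] rows).
#' @param bin_width bin width in bp.
#' @param total_mapped total mapped reads for normalization; defaults to
#'   `nrow(alignments)`.
#' @param chrom_len optional named vector of chromosome lengths; defaults to
#'   the maximum aligned position per chromosome (bins tile to that point).
#' @return data.frame `chrom`, `start` (0-based), `end`, `rpkm`.
#' @export
coverage_track <- function(alignments, bin_width = 100L, total_mapped = NULL,
                           chrom_len = NULL) {
  if (is.null(total_mapped)) total_mapped <- nrow(alignments)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      rpkm = numeric(), stringsAsFactors = FALSE)
  if (total_mapped == 0L) {
    warning("total_mapped is zero; empty coverage track")
    return(empty)
  }
  a <- alignments[!alignments$is_unmapped & !is.na(alignments$pos), ,
                  drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  out <- list()
  for (ch in sort(unique(a$chrom))) {
    pos <- a$pos[a$chrom == ch]
    L <- if (!is.null(chrom_len) && ch %in% names(chrom_len)) chrom_len[[ch]]
         else max(pos)
    n_bins <- ceiling(L / bin_width)
    bin <- pmin(((pos - 1L) %/% bin_width) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    out[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(n_bins) - 1L) * bin_width,
      end = pmin(seq_len(n_bins) * bin_width, as.integer(n_bins * bin_width)),
      rpkm = counts / ((bin_width / 1000) * (total_mapped / 1e6)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a coverage track as bedGraph (0-based half-open)
#'
#' @param track data.frame from [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%g", track$chrom, track$start, track$end,
                   track$rpkm)
  writeLines(lines, path)
  invisible(path)
}
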