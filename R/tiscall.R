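#' Reconstruct chimeric junctions from filtered T-DNA hits
#'
#' Restores the genomic alignment of each retained soft-clipped read and
#' derives the exact cleavage site. The clip side fixes the junction
#' configuration: a right clip means the reference precedes the T-DNA along
#' the + strand (config "R", junction at the last aligned base), a left clip
#' means the T-DNA precedes the reference (config "L", junction at the first
#' aligned base). Clips are stored in reference orientation, so a + strand
#' construct hit means the construct runs co-directionally with the
#' reference (orientation "+").
#'
#' @param hits data.frame from [align_clips()] after [filter_hits()] (soft-clip
#'   columns joined with hit columns).
#' @return data.frame of chimeric reads: `read_id`, `replicate_id`, `chrom`,
#'   `junction` (1-based), `config` ("R"/"L"), `orientation` ("+"/"-"),
#'   `construct_id`, `t_junction` (construct coordinate adjoining the
#'   breakpoint), `genome_seg_len`, `tdna_seg_len`, `full_seq`.
#' @export
reconstruct_junctions <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(read_id = character(), replicate_id = character(),
                      chrom = character(), junction = integer(),
                      config = character(), orientation = character(),
                      construct_id = character(), t_junction = integer(),
                      genome_seg_len = integer(), tdna_seg_len = integer(),
                      full_seq = character(), stringsAsFactors = FALSE))
  config <- ifelse(hits$clip_side == "right", "R", "L")
  junction <- ifelse(config == "R", hits$aligned_end, hits$aligned_start)
  orientation <- hits$t_strand
  # construct coordinate adjoining the breakpoint: for config R the junction
  # meets the first clip base (construct start on +, end on -); for config L
  # it meets the last clip base (construct end on +, start on -)
  t_junction <- ifelse(config == "R",
                       ifelse(orientation == "+", hits$t_start, hits$t_end),
                       ifelse(orientation == "+", hits$t_end, hits$t_start))
  data.frame(read_id = hits$read_id, replicate_id = hits$replicate_id,
             chrom = hits$chrom, junction = as.integer(junction),
             config = config, orientation = orientation,
             construct_id = hits$construct_id,
             t_junction = as.integer(t_junction),
             genome_seg_len = hits$genome_match_len,
             tdna_seg_len = hits$matched_len,
             full_seq = hits$read_seq, stringsAsFactors = FALSE)
}

#' Default evidence weights and score threshold
#'
#' Supporting reads at a candidate insertion site fall into five groups
#' relative to the reference read: (1) chimeric reads with a different
#' genome/T-DNA split ratio, (2) reads one base away from the reference,
#' (3) reads identical to the reference from a different biological
#' replicate, (4) chimeric reads with nearby but non-identical junctions,
#' (5) discordant pairs anchored near the junction. The defaults weight the
#' groups 700/300/300/1/1 with a pass threshold of 1000, so a true site
#' typically needs the reference read plus two supporters from groups 1-3.
#'
#' @param w1,w2,w3,w4,w5 non-negative group weights.
#' @param threshold score at or above which a candidate passes.
#' @return a `scoring_weights` list.
#' @export
scoring_weights <- function(w1 = 700, w2 = 300, w3 = 300, w4 = 1, w5 = 1,
                            threshold = 1000) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5)
  if (any(w < 0)) stop("weights must be non-negative")
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(w = unname(w), threshold = threshold),
            class = "scoring_weights")
}

#' Weighted confidence score of a candidate insertion site
#'
#' `score = sum(g_i * w_i)` over the five supporter groups; the reference
#' read itself contributes nothing.
#'
#' @param g1,g2,g3,g4,g5 supporter counts (non-negative).
#' @param weights a [scoring_weights()] object.
#' @return numeric score(s); exact integer arithmetic with default weights.
#' @export
score_candidate <- function(g1, g2, g3, g4, g5 = 0,
                            weights = scoring_weights()) {
  g <- cbind(g1, g2, g3, g4, g5)
  if (any(g < 0)) stop("supporter counts must be non-negative")
  as.numeric(g %*% weights$w)
}

#' Cluster chimeric reads into candidate insertion sites and classify
#' supporters
#'
#' Chimeric reads from all replicates are merged, then grouped by
#' (chromosome, configuration). Within a group the reference read is the
#' member maximizing `min(genome_seg_len, tdna_seg_len)` (ties by
#' lexicographic read id); all members whose junction lies within `w` bases
#' of the reference junction join that candidate, and the procedure repeats
#' on the remainder. Each non-reference member is assigned to exactly one
#' group by priority: identical sequence from a different replicate (G3);
#' same junction, sequence at Hamming distance 1 (G2); same junction,
#' different split ratio (G1); junction within `w` but unequal (G4).
#' Identical sequence from the same replicate is a residual duplicate and is
#' dropped, as is anything matching no rule.
#'
#' @param chimeric data.frame from [reconstruct_junctions()] (all replicates).
#' @param w clustering window in bp around the reference junction.
#' @param weights a [scoring_weights()] object.
#' @return data.frame of candidates: locus columns, reference read id,
#'   `g1..g5` counts (g5 = 0 until discordant support is attached),
#'   `n_dropped`, `score`, `replicates` (comma-joined), `n_reads` (reference
#'   plus classified supporters), `supporting_reads` (comma-joined ids).
#' @export
build_candidates <- function(chimeric, w = 10L, weights = scoring_weights()) {
  empty <- data.frame(chrom = character(), junction = integer(),
                      config = character(), orientation = character(),
                      construct_id = character(), t_junction = integer(),
                      ref_read_id = character(), g1 = integer(),
                      g2 = integer(), g3 = integer(), g4 = integer(),
                      g5 = integer(), n_dropped = integer(), score = numeric(),
                      replicates = character(), n_reads = integer(),
                      supporting_reads = character(), stringsAsFactors = FALSE)
  if (nrow(chimeric) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(chimeric$chrom, chimeric$config, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    pool <- chimeric[chimeric$chrom == parts[1] & chimeric$config == parts[2], ,
                     drop = FALSE]
    while (nrow(pool) > 0L) {
      depth <- pmin(pool$genome_seg_len, pool$tdna_seg_len)
      o <- order(-depth, pool$read_id, pool$replicate_id)
      ref <- pool[o[1L], , drop = FALSE]
      in_cand <- abs(pool$junction - ref$junction) <= w
      members <- pool[in_cand, , drop = FALSE]
      pool <- pool[!in_cand, , drop = FALSE]
      out[[length(out) + 1L]] <- classify_members(ref, members, weights)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$junction, res$config), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# classify the members of one candidate against its reference read
classify_members <- function(ref, members, weights) {
  sup <- members[!(members$read_id == ref$read_id &
                   members$replicate_id == ref$replicate_id &
                   members$full_seq == ref$full_seq), , drop = FALSE]
  # guard against the reference row itself only (same id+rep+seq), not
  # genuine duplicates of it from other replicates
  if (nrow(members) - nrow(sup) > 1L) {
    dup_ref <- members[members$read_id == ref$read_id &
                       members$replicate_id == ref$replicate_id &
                       members$full_seq == ref$full_seq, , drop = FALSE]
    sup <- rbind(sup, dup_ref[-1L, , drop = FALSE])
  }
  g <- c(0L, 0L, 0L, 0L, 0L)
  dropped <- 0L
  kept_ids <- character(0)
  for (i in seq_len(nrow(sup))) {
    s <- sup[i, ]
    same_seq <- s$full_seq == ref$full_seq
    same_junction <- s$junction == ref$junction
    grp <- NA_integer_
    if (same_seq && s$replicate_id != ref$replicate_id) {
      grp <- 3L
    } else if (same_junction && nchar(s$full_seq) == nchar(ref$full_seq) &&
               hamming(s$full_seq, ref$full_seq) == 1L) {
      grp <- 2L
    } else if (same_junction && s$genome_seg_len != ref$genome_seg_len) {
      grp <- 1L
    } else if (!same_junction) {
      grp <- 4L
    }
    if (is.na(grp)) dropped <- dropped + 1L
    else { g[grp] <- g[grp] + 1L; kept_ids <- c(kept_ids, s$read_id) }
  }
  reps <- sort(unique(members$replicate_id))
  data.frame(chrom = ref$chrom, junction = ref$junction, config = ref$config,
             orientation = ref$orientation, construct_id = ref$construct_id,
             t_junction = ref$t_junction, ref_read_id = ref$read_id,
             g1 = g[1], g2 = g[2], g3 = g[3], g4 = g[4], g5 = g[5],
             n_dropped = dropped,
             score = score_candidate(g[1], g[2], g[3], g[4], g[5], weights),
             replicates = paste(reps, collapse = ","),
             n_reads = 1L + sum(g[1:4]),
             supporting_reads = paste(kept_ids, collapse = ","),
             stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Attach discordant-pair (Group 5) support to candidates
#'
#' A discordant pair supports a candidate when its genomic anchor lies within
#' `D` bp of the junction on the same chromosome, faces the junction (the
#' anchor's read orientation points at it), and its non-genomic mate aligns
#' to the construct and survives [filter_hits()]. Scores are recomputed.
#'
#' @param candidates data.frame from [build_candidates()].
#' @param discordant data.frame from [extract_discordant_candidates()].
#' @param constructs list of [tdna_construct()].
#' @param D proximity window in bp.
#' @param weights a [scoring_weights()] object.
#' @param m,l1,l2,d filtering parameters, as in [filter_hits()].
#' @return candidates with updated `g5` and `score`.
#' @export
attach_discordant_support <- function(candidates, discordant, constructs,
                                      D = 1000L, weights = scoring_weights(),
                                      m = 1L, l1 = 18L, l2 = 30L, d = 200L) {
  if (nrow(candidates) == 0L || is.null(discordant) || nrow(discordant) == 0L)
    return(candidates)
  if (inherits(constructs, "tdna_construct")) constructs <- list(constructs)
  # align each non-genomic mate once
  mate_ok <- logical(nrow(discordant))
  for (i in seq_len(nrow(discordant))) {
    best <- NULL
    for (cons in constructs) {
      h <- align_clip_to_tdna(discordant$other_seq[i], cons, m = m, l1 = l1)
      if (!is.null(h) && (is.null(best) || h$matched_len > best$matched_len))
        best <- h
    }
    mate_ok[i] <- !is.null(best) &&
      nrow(filter_hits(best, constructs, d = d, l1 = l1, l2 = l2, m = m)) == 1L
  }
  for (k in seq_len(nrow(candidates))) {
    j <- candidates$junction[k]
    same <- discordant$chrom == candidates$chrom[k]
    dist <- ifelse(j >= discordant$anchor_start & j <= discordant$anchor_end, 0L,
                   pmin(abs(j - discordant$anchor_start),
                        abs(j - discordant$anchor_end)))
    facing <- ifelse(discordant$anchor_strand == "+",
                     j >= discordant$anchor_start, j <= discordant$anchor_end)
    candidates$g5[k] <- sum(same & mate_ok & facing & dist <= D)
  }
  candidates$score <- score_candidate(candidates$g1, candidates$g2,
                                      candidates$g3, candidates$g4,
                                      candidates$g5, weights)
  candidates
}

#' Call insertion sites from scored candidates
#'
#' Candidates whose junction falls inside a blacklist interval are removed
#' before reporting. The rest are marked pass (`score >= threshold`) or fail,
#' passing calls are annotated with every overlapping gene feature, and the
#' result is sorted by (chromosome, junction).
#'
#' @param candidates scored candidates from [build_candidates()].
#' @param threshold pass threshold (a score exactly at the threshold passes).
#' @param blacklist `NULL`, a BED path (0-based half-open), or a `GRanges`.
#' @param annotation `NULL`, a GFF3 path (1-based closed), or a `GRanges`
#'   of gene features.
#' @return candidates with `status` ("pass"/"fail") and `genes` columns;
#'   blacklisted rows removed.
#' @export
call_tis <- function(candidates, threshold = 1000, blacklist = NULL,
                     annotation = NULL) {
  bl <- load_intervals(blacklist, "blacklist")
  ann <- load_intervals(annotation, "annotation")
  out <- candidates
  if (!is.null(bl) && nrow(out) > 0L) {
    pts <- GenomicRanges::GRanges(out$chrom, IRanges(out$junction, out$junction))
    hit <- GenomicRanges::countOverlaps(pts, bl) > 0L
    out <- out[!hit, , drop = FALSE]
  }
  out$status <- ifelse(out$score >= threshold, "pass", "fail")
  out$genes <- rep("", nrow(out))
  if (!is.null(ann) && nrow(out) > 0L) {
    if ("type" %in% names(S4Vectors::mcols(ann)) &&
        any(S4Vectors::mcols(ann)$type == "gene"))
      ann <- ann[S4Vectors::mcols(ann)$type == "gene"]
    pts <- GenomicRanges::GRanges(out$chrom, IRanges(out$junction, out$junction))
    ov <- GenomicRanges::findOverlaps(pts, ann)
    nm <- feature_names(ann)
    if (length(ov) > 0L) {
      agg <- tapply(nm[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov),
                    function(x) paste(unique(x), collapse = ","))
      out$genes[as.integer(names(agg))] <- unname(agg)
    }
  }
  out <- out[order(out$chrom, out$junction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

load_intervals <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "GRanges")) return(x)
  if (!is.character(x) || !file.exists(x))
    stop("cannot read ", what, " file: ", x)
  tryCatch(rtracklayer::import(x),
           error = function(e) stop("cannot read ", what, " file: ", x,
                                    " (", conditionMessage(e), ")"))
}

feature_names <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("Name", "ID", "gene_id", "name")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      if (any(!is.na(v))) return(ifelse(is.na(v), "feature", v))
    }
  }
  rep("feature", length(gr))
}

#' Evaluate calls against a truth set
#'
#' Calls are matched one-to-one to truth junctions on the same chromosome by
#' greedy nearest distance within `match_tolerance`. TP is the count of
#' annotated and identified sites, FN annotated-but-missed, FP
#' identified-but-unannotated; sensitivity = TP/(TP+FN), precision =
#' TP/(TP+FP), F1 = 2*S*P/(S+P) (0 when TP = 0).
#'
#' @param calls data.frame with `chrom` and `junction` (typically passing
#'   calls).
#' @param truth data.frame with `chrom` and `junction`.
#' @param match_tolerance maximum |call - truth| distance in bp.
#' @return list with `TP`, `FN`, `FP`, `sensitivity`, `precision`, `F1`.
#' @export
evaluate_calls <- function(calls, truth, match_tolerance = 100L) {
  nc <- nrow(calls); nt <- nrow(truth)
  pairs <- NULL
  if (nc > 0L && nt > 0L) {
    grid <- expand.grid(ci = seq_len(nc), ti = seq_len(nt))
    grid$dist <- abs(calls$junction[grid$ci] - truth$junction[grid$ti])
    grid <- grid[calls$chrom[grid$ci] == truth$chrom[grid$ti] &
                 grid$dist <= match_tolerance, , drop = FALSE]
    grid <- grid[order(grid$dist, grid$ci, grid$ti), , drop = FALSE]
    used_c <- logical(nc); used_t <- logical(nt)
    for (i in seq_len(nrow(grid))) {
      ci <- grid$ci[i]; ti <- grid$ti[i]
      if (!used_c[ci] && !used_t[ti]) { used_c[ci] <- TRUE; used_t[ti] <- TRUE }
    }
    TP <- sum(used_c)
  } else TP <- 0L
  eval_from_counts(TP, FN = nt - TP, FP = nc - TP)
}

#' Evaluation metrics from raw counts
#'
#' @param TP,FN,FP true-positive, false-negative and false-positive counts.
#' @return list with the counts, `sensitivity`, `precision`, `F1`.
#' @export
eval_from_counts <- function(TP, FN, FP) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (TP > 0) 2 * sens * prec / (sens + prec) else 0
  list(TP = TP, FN = FN, FP = FP,
       sensitivity = sens, precision = prec, F1 = f1)
}
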