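# joined soft-clip + hit rows for junction reconstruction
chim_input <- function(clip_side, aligned_start, aligned_end, t_strand,
                       t_start = 10L, t_end = 49L) {
  data.frame(read_id = "r1", replicate_id = "rep1", chrom = "chr1",
             aligned_start = aligned_start, aligned_end = aligned_end,
             clip_side = clip_side, clip_seq = strrep("A", 40),
             clip_quals = strrep("I", 40), clip_len = 40L, read_len = 100L,
             genome_match_len = 60L, read_seq = strrep("A", 100),
             genome_seq = strrep("A", 60), construct_id = "c1",
             t_start = t_start, t_end = t_end, t_strand = t_strand,
             mode = "end2end", matched_len = 40L, mismatches = 0L,
             q_start = 1L, q_end = 40L, border_distance = 9L,
             stringsAsFactors = FALSE)
}

test_that("junction reconstruction follows the clip-side/strand case table", {
  # right clip, + strand: junction at the last aligned base, config R
  cr <- reconstruct_junctions(chim_input("right", 1000L, 1059L, "+"))
  expect_equal(cr$junction, 1059L)
  expect_equal(cr$config, "R")
  expect_equal(cr$orientation, "+")
  expect_equal(cr$t_junction, 10L)  # construct start adjoins the breakpoint

  # left clip, + strand: junction at the first aligned base, config L
  cl <- reconstruct_junctions(chim_input("left", 500L, 569L, "+"))
  expect_equal(cl$junction, 500L)
  expect_equal(cl$config, "L")
  expect_equal(cl$orientation, "+")
  expect_equal(cl$t_junction, 49L)  # construct end adjoins the breakpoint

  # flipping the hit strand flips orientation (and the adjoining construct
  # coordinate) and nothing else
  crm <- reconstruct_junctions(chim_input("right", 1000L, 1059L, "-"))
  expect_equal(crm$orientation, "-")
  expect_equal(crm$t_junction, 49L)
  expect_equal(crm[c("junction", "config")], cr[c("junction", "config")])
})

test_that("supporters are classified into the five evidence groups", {
  set.seed(21)
  base <- rand_dna(100)
  one_off <- `substr<-`(base, 10, 10, setdiff(c("A","C","G","T"), substr(base, 10, 10))[1])
  members <- rbind(
    make_chim("a_ref", 1000L, 50L, 50L, base),                        # reference
    make_chim("b_g1",  1000L, 60L, 40L, rand_dna(100)),               # split 60/40
    make_chim("c_g2",  1000L, 50L, 50L, one_off),                     # 1 mismatch
    make_chim("d_g3",  1000L, 50L, 50L, base, replicate_id = "rep2"), # other replicate
    make_chim("e_g4",  1004L, 55L, 45L, rand_dna(100)))               # nearby junction
  cand <- build_candidates(members, w = 10L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$ref_read_id, "a_ref")
  expect_equal(unlist(cand[, c("g1", "g2", "g3", "g4")], use.names = FALSE),
               c(1L, 1L, 1L, 1L))
  expect_equal(cand$score, 700 + 300 + 300 + 1)

  # an exact copy of the reference from the same replicate is residual
  # duplication: dropped, counts unchanged
  cand2 <- build_candidates(rbind(members,
                                  make_chim("z_dup", 1000L, 50L, 50L, base)),
                            w = 10L)
  expect_equal(unlist(cand2[, c("g1", "g2", "g3", "g4")], use.names = FALSE),
               c(1L, 1L, 1L, 1L))
  expect_equal(cand2$n_dropped, 1L)

  # single member: it is the reference, all groups zero
  c1 <- build_candidates(make_chim("solo", 500L, 50L, 50L, base))
  expect_equal(c1$score, 0)
  expect_equal(c1$ref_read_id, "solo")

  expect_equal(nrow(build_candidates(members[0, ])), 0L)
})

test_that("the reference read maximizes the smaller junction segment", {
  set.seed(22)
  members <- rbind(
    make_chim("shallow", 1000L, 90L, 10L, rand_dna(100)),
    make_chim("deep",    1000L, 45L, 55L, rand_dna(100)),
    make_chim("mid",     1000L, 70L, 30L, rand_dna(100)))
  cand <- build_candidates(members)
  expect_equal(cand$ref_read_id, "deep")  # min(45,55) = 45 is maximal
})

test_that("classification partitions every non-reference member", {
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(2:12, 1)
    members <- do.call(rbind, lapply(seq_len(n), function(i) {
      g <- sample(30:70, 1)
      make_chim(paste0("m", i), 1000L + sample(-8:8, 1), g, 100L - g,
                rand_dna(100), replicate_id = sample(c("rep1", "rep2"), 1))
    }))
    cand <- build_candidates(members, w = 20L)
    expect_equal(sum(cand$g1 + cand$g2 + cand$g3 + cand$g4 + cand$n_dropped) +
                   nrow(cand), n)
  }
})

test_that("confidence scores are exact weighted sums, additive and monotone", {
  w <- scoring_weights()
  expect_identical(w$w, c(700, 300, 300, 1, 1))
  expect_equal(w$threshold, 1000)
  expect_equal(score_candidate(1, 0, 1, 0, 0), 1000)
  expect_equal(score_candidate(0, 0, 0, 0, 0), 0)
  expect_equal(score_candidate(2, 0, 0, 5, 10), 1415)
  expect_error(score_candidate(-1, 0, 0, 0, 0), "non-negative")

  set.seed(31)
  for (i in 1:20) {
    a <- sample(0:5, 5, replace = TRUE)
    b <- sample(0:5, 5, replace = TRUE)
    sa <- score_candidate(a[1], a[2], a[3], a[4], a[5])
    sb <- score_candidate(b[1], b[2], b[3], b[4], b[5])
    ab <- a + b
    expect_equal(score_candidate(ab[1], ab[2], ab[3], ab[4], ab[5]), sa + sb)
    expect_true(score_candidate(a[1] + 1, a[2], a[3], a[4], a[5]) >= sa)
  }
})

test_that("calls pass at the threshold, blacklisted junctions never appear", {
  at <- data.frame(chrom = "chr1", junction = 5000L, config = "R",
                   orientation = "+", construct_id = "c1", t_junction = 1L,
                   ref_read_id = "r", g1 = 1L, g2 = 0L, g3 = 1L, g4 = 0L,
                   g5 = 0L, n_dropped = 0L, score = 1000,
                   replicates = "rep1,rep2", n_reads = 3L,
                   supporting_reads = "a,b", stringsAsFactors = FALSE)
  below <- at; below$junction <- 7000L; below$score <- 999
  blk <- at; blk$junction <- 9000L
  out <- call_tis(rbind(at, below, blk), threshold = 1000,
                  blacklist = GenomicRanges::GRanges("chr1", IRanges::IRanges(8900, 9100)))
  expect_equal(out$junction, c(5000L, 7000L))
  expect_equal(out$status, c("pass", "fail"))
  expect_false(9000L %in% out$junction)
})

test_that("passing calls are annotated with overlapping genes", {
  at <- data.frame(chrom = "chr1", junction = 5000L, config = "R",
                   orientation = "+", construct_id = "c1", t_junction = 1L,
                   ref_read_id = "r", g1 = 2L, g2 = 0L, g3 = 0L, g4 = 0L,
                   g5 = 0L, n_dropped = 0L, score = 1400,
                   replicates = "rep1", n_reads = 3L, supporting_reads = "a,b",
                   stringsAsFactors = FALSE)
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(4000, 6000), c(5500, 6500)))
  S4Vectors::mcols(ann)$type <- "gene"
  S4Vectors::mcols(ann)$Name <- c("GENE1", "GENE2")
  out <- call_tis(at, annotation = ann)
  expect_equal(out$genes, "GENE1")
  # a GFF3 file on disk works the same way
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t4000\t5500\t.\t+\t.\tID=g1;Name=GENE1"), gff)
  expect_equal(call_tis(at, annotation = gff)$genes, "GENE1")
  expect_error(call_tis(at, annotation = "/nonexistent.gff3"), "cannot read")
})

test_that("evaluation reproduces the metric formulas from matched counts", {
  m <- eval_from_counts(TP = 42L, FN = 7L, FP = 12L)
  expect_equal(round(m$sensitivity, 2), 0.86)   # 42 / 49
  expect_equal(round(m$precision, 2), 0.78)     # 42 / 54
  m2 <- eval_from_counts(TP = 46L, FN = 8L, FP = 8L)
  expect_equal(round(m2$sensitivity, 2), 0.85)  # 46 / 54
  m0 <- eval_from_counts(0L, 5L, 3L)
  expect_equal(c(m0$sensitivity, m0$precision, m0$F1), c(0, 0, 0))
  expect_equal(m$F1, 2 * m$sensitivity * m$precision /
                 (m$sensitivity + m$precision))
})

test_that("call-truth matching is greedy, nearest-first and one-to-one", {
  calls <- data.frame(chrom = "chr1", junction = c(100L, 106L, 5000L))
  truth <- data.frame(chrom = "chr1", junction = c(103L, 9999L))
  m <- evaluate_calls(calls, truth, match_tolerance = 10L)
  expect_equal(m$TP, 1L)   # only one call can take the 103 truth entry
  expect_equal(m$FP, 2L)
  expect_equal(m$FN, 1L)
  # chromosome must match
  calls2 <- data.frame(chrom = "chr2", junction = 103L)
  expect_equal(evaluate_calls(calls2, truth, 10L)$TP, 0L)
})

test_that("discordant pairs add Group-5 support only near and facing the junction", {
  set.seed(51)
  cons <- tdna_construct("c1", rand_dna(600))
  cand <- data.frame(chrom = "chr1", junction = 10000L, config = "R",
                     orientation = "+", construct_id = "c1", t_junction = 1L,
                     ref_read_id = "r", g1 = 1L, g2 = 0L, g3 = 0L, g4 = 0L,
                     g5 = 0L, n_dropped = 0L, score = 700,
                     replicates = "rep1", n_reads = 2L, supporting_reads = "a",
                     stringsAsFactors = FALSE)
  mate_tdna <- substr(cons$sequence, 50, 149)  # passes border filter
  disc <- data.frame(
    pair_id = c("near", "far", "downstream_rev"),
    replicate_id = "rep1", chrom = "chr1",
    anchor_start = c(9600L, 4000L, 10300L),
    anchor_end = c(9699L, 4099L, 10399L),
    anchor_strand = c("+", "+", "-"),
    other_seq = mate_tdna, other_quals = strrep("I", 100),
    stringsAsFactors = FALSE)
  up <- attach_discordant_support(cand, disc, cons, D = 1000L)
  # "near" anchors 300 bp upstream facing the junction; "far" is 6 kb away;
  # "downstream_rev" sits past the junction on - strand, pointing back at it
  expect_equal(up$g5, 2L)
  expect_equal(up$score, 700 + 2)

  # a mate that does not align to the construct contributes nothing
  disc$other_seq <- strrep("A", 100)
  expect_equal(attach_discordant_support(cand, disc, cons, D = 1000L)$g5, 0L)
})
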