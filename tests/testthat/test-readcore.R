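test_that("clip extraction follows CIGAR consumption rules", {
  # no S op -> no record
  expect_equal(nrow(extract_soft_clips(make_aln(cigar = "100M"))), 0L)

  # right clip: 60M40S at chrom1:1000
  r <- extract_soft_clips(make_aln(pos = 1000L, cigar = "60M40S"),
                          r_min_match_fraction = 0.5, min_clip = 18L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$clip_side, "right")
  expect_equal(r$clip_len, 40L)
  expect_equal(c(r$aligned_start, r$aligned_end), c(1000L, 1059L))
  expect_equal(r$clip_seq, substr(r$read_seq, 61, 100))

  # left clip: 30S70M at chrom1:500; discarded when the anchored fraction
  # requirement rises above what the read provides (70 < 0.8 * 100)
  a <- make_aln(pos = 500L, cigar = "30S70M")
  r <- extract_soft_clips(a, r_min_match_fraction = 0.5, min_clip = 18L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$clip_side, "left")
  expect_equal(r$clip_len, 30L)
  expect_equal(c(r$aligned_start, r$aligned_end), c(500L, 569L))
  expect_equal(nrow(extract_soft_clips(a, r_min_match_fraction = 0.8)), 0L)
})

test_that("reads clipped at both ends yield two records and hard clips none", {
  r <- extract_soft_clips(make_aln(cigar = "20S60M20S"),
                          r_min_match_fraction = 0.5, min_clip = 18L)
  expect_equal(nrow(r), 2L)
  expect_setequal(r$clip_side, c("left", "right"))
  # the genomic portion excludes both clips
  expect_true(all(nchar(r$genome_seq) == 60L))

  expect_equal(nrow(extract_soft_clips(make_aln(cigar = "10H90M"))), 0L)
  # H before a leading S does not change the clip side
  r <- extract_soft_clips(make_aln(cigar = "5H30S65M"),
                          r_min_match_fraction = 0.5, min_clip = 18L)
  expect_equal(r$clip_side, "left")
})

test_that("splice gaps (N) consume reference but not query", {
  r <- extract_soft_clips(make_aln(pos = 100L, cigar = "40M500N40M20S"),
                          r_min_match_fraction = 0.5, min_clip = 18L)
  expect_equal(r$clip_len, 20L)
  expect_equal(r$genome_match_len, 80L)
  expect_equal(r$aligned_end, 100L + 40L + 500L + 40L - 1L)
})

test_that("malformed CIGARs and missing sequences are skipped with a warning", {
  a <- rbind(make_aln(read_id = "good", cigar = "60M40S"),
             make_aln(read_id = "bad1", cigar = "60Q40S", seq = strrep("A", 100)),
             make_aln(read_id = "bad2", cigar = "60M40S", seq = "*"))
  expect_warning(r <- extract_soft_clips(a, r_min_match_fraction = 0.5,
                                         min_clip = 18L), "skipped")
  expect_equal(r$read_id, "good")
})

test_that("CIGAR accounting holds on every extracted record", {
  set.seed(42)
  cigars <- c("50M50S", "25S75M", "10S80M10S", "40M2I38M20S", "30S30M5D40M",
              "18S40M200N42M")
  a <- do.call(rbind, lapply(seq_along(cigars), function(i)
    make_aln(read_id = paste0("r", i), cigar = cigars[i])))
  r <- extract_soft_clips(a, r_min_match_fraction = 0.2, min_clip = 1L)
  # clip + genomic query portion + any other clip = read length
  other_clip <- vapply(seq_len(nrow(r)), function(i) {
    same <- r[r$read_id == r$read_id[i], ]
    if (nrow(same) == 2L) same$clip_len[same$clip_side != r$clip_side[i]] else 0L
  }, integer(1))
  expect_equal(r$clip_len + nchar(r$genome_seq) + other_clip, r$read_len)
})

test_that("duplicate removal is per-replicate, idempotent and order-independent", {
  expect_equal(nrow(deduplicate(extract_soft_clips(make_aln(cigar = "1M")))), 0L)

  a <- make_aln(read_id = "a", cigar = "60M40S")
  b <- make_aln(read_id = "b", cigar = "60M40S")  # same span, side, sequence
  r <- extract_soft_clips(rbind(a, b), r_min_match_fraction = 0.5)
  expect_equal(nrow(deduplicate(r)), 1L)

  # identical placements in different replicates both survive: cross-replicate
  # identity is Group-3 evidence, not duplication
  b2 <- make_aln(read_id = "b", cigar = "60M40S", replicate_id = "rep2")
  r2 <- extract_soft_clips(rbind(a, b2), r_min_match_fraction = 0.5)
  expect_equal(nrow(deduplicate(r2)), 2L)

  # property: idempotent and permutation-invariant
  set.seed(1)
  pool <- do.call(rbind, lapply(1:12, function(i)
    make_aln(read_id = paste0("r", i), pos = sample(c(100L, 200L), 1),
             cigar = sample(c("60M40S", "40S60M"), 1),
             replicate_id = sample(c("rep1", "rep2"), 1))))
  r <- extract_soft_clips(pool, r_min_match_fraction = 0.5)
  d1 <- deduplicate(r)
  expect_identical(deduplicate(d1), d1)
  for (k in 1:5) {
    shuf <- r[sample(nrow(r)), , drop = FALSE]
    expect_identical(deduplicate(shuf), d1)
  }
})

test_that("cleaved reads respect the clip-length and poly(N) rules", {
  empty <- extract_soft_clips(make_aln(cigar = "1M"))
  expect_equal(nrow(make_cleaved_reads(empty)), 0L)

  # l1 boundary is inclusive
  r18 <- extract_soft_clips(make_aln(cigar = "82M18S"), r_min_match_fraction = 0.5)
  expect_equal(nrow(make_cleaved_reads(r18, l1 = 18L)), 1L)
  r17 <- extract_soft_clips(make_aln(cigar = "83M17S"), r_min_match_fraction = 0.5)
  expect_equal(nrow(make_cleaved_reads(r17, l1 = 18L)), 0L)

  # genomic portion 85% N -> excluded at polyN_max 0.8; clean clip is kept
  seq85 <- paste0(strrep("N", 68), strrep("A", 12), strrep("ACGT", 5))
  a <- make_aln(cigar = "80M20S", seq = seq85)
  r <- extract_soft_clips(a, r_min_match_fraction = 0.5)
  expect_equal(nrow(make_cleaved_reads(r, l1 = 18L, polyN_max = 0.8)), 0L)
  seq50 <- paste0(strrep("N", 40), strrep("A", 40), strrep("ACGT", 5))
  r <- extract_soft_clips(make_aln(cigar = "80M20S", seq = seq50),
                          r_min_match_fraction = 0.5)
  expect_equal(nrow(make_cleaved_reads(r, l1 = 18L, polyN_max = 0.8)), 1L)

  # no cleaved read shorter than l1 under any l1
  set.seed(2)
  pool <- do.call(rbind, lapply(1:20, function(i)
    make_aln(read_id = paste0("r", i),
             cigar = paste0(100L - i, "M", i, "S"))))
  r <- extract_soft_clips(pool, r_min_match_fraction = 0.2, min_clip = 1L)
  for (l1 in c(5L, 10L, 18L))
    expect_true(all(make_cleaved_reads(r, l1 = l1)$clip_len >= l1))
})

test_that("cleaved FASTQ is standard 4-line Phred+33", {
  r <- extract_soft_clips(make_aln(cigar = "60M40S"), r_min_match_fraction = 0.5)
  cl <- make_cleaved_reads(r, l1 = 18L)
  p <- tempfile(fileext = ".fastq")
  write_cleaved_fastq(cl, p)
  lines <- readLines(p)
  expect_equal(length(lines), 4L)
  expect_match(lines[1], "^@")
  expect_equal(lines[3], "+")
  expect_equal(nchar(lines[2]), nchar(lines[4]))
})

test_that("discordant candidates require exactly one confident genomic anchor", {
  # properly paired, both mapped -> nothing
  both <- rbind(
    make_aln(read_id = "p1", pos = 1000L, cigar = "100M", flag = 1L + 2L + 64L),
    make_aln(read_id = "p1", pos = 1200L, cigar = "100M", flag = 1L + 2L + 128L))
  expect_equal(nrow(extract_discordant_candidates(both)), 0L)

  # one mate mapped at chrom2:10000-10099, the other unmapped
  pair <- rbind(
    make_aln(read_id = "d1", chrom = "chr2", pos = 10000L, cigar = "100M",
             flag = 1L + 8L + 64L),
    make_aln(read_id = "d1", chrom = NA, pos = NA_integer_, cigar = NA,
             seq = strrep("T", 100), flag = 1L + 4L + 128L, mapq = 0L))
  d <- extract_discordant_candidates(pair, min_mapq = 30L)
  expect_equal(nrow(d), 1L)
  expect_equal(d$other_seq, strrep("T", 100))
  expect_equal(c(d$anchor_start, d$anchor_end), c(10000L, 10099L))

  # single-end input -> empty, with a message
  se <- make_aln(cigar = "100M")
  expect_message(d0 <- extract_discordant_candidates(se), "paired")
  expect_equal(nrow(d0), 0L)
})
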