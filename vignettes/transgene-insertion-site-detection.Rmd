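---
title: "Detecting transgene insertion sites from short-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transgene insertion sites from short-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiscaller)
```

## The problem

*Agrobacterium*-mediated transformation integrates a transfer DNA (T-DNA)
segment at essentially random positions of a host plant genome. Knowing the
insertion sites (TISs) matters twice over: the insertion disrupts whatever it
lands in, and lines frequently carry more insertions than their annotation
records. Dedicated assays (flanking-sequence PCR, whole-genome sequencing) are
expensive relative to the RNA-seq data that most plant studies already
generate, and in gene-dense genomes a large fraction of the genome is
transcribed, so transcriptome reads routinely cross insertion junctions.

`tiscaller` mines standard short-read alignments (RNA-seq, ChIP-seq input, or
WGS; SAM/BAM with soft clips preserved) for reads that span a genome/T-DNA
junction, and reports insertion sites with a quantitative confidence score.

## The method

The pipeline has four stages.

**1. Soft-clip mining (`extract_soft_clips`, `deduplicate`,
`make_cleaved_reads`).** A read crossing an insertion junction aligns to the
genome only partially; the aligner soft-clips the T-DNA-derived remainder
(CIGAR `S`). Every `S` operation whose read keeps at least a fraction `r` of
its bases genome-aligned yields one record (a read clipped at both ends yields
two). `r` defaults by read length — 0.67 under 100 bp, 0.50 for 100–124 bp,
0.33 for 125–151 bp — because shorter reads need a proportionally larger
genomic anchor to be trustworthy. PCR duplicates are collapsed per replicate
on (span, clip side, full read sequence); the full sequence is deliberately
part of the key so reads with different genome/T-DNA split ratios — the
strongest class of supporting evidence — are never merged. Clips of at least
`l1` (default 18 bp) whose genomic portion is less than 80% `N` become
*cleaved reads*.

**2. Construct alignment (`align_clips`, `filter_hits`).** Each cleaved read
is aligned to the supplied construct sequence(s) on both strands, ungapped. A
whole-clip (end-to-end) placement within the mismatch budget `m` (default 1)
is preferred; otherwise the best local window — contiguous, starting and
ending on a match, at most `m` mismatches — is taken, maximizing matched
length with ties broken by fewer mismatches, smaller construct coordinate,
then + strand. Because integration proceeds through the border repeats, hits
within `d` (default 200 bp) of a border pass at the mild length threshold
`l1`, while hits deeper inside the construct must reach `l2` (default 30 bp);
hits with more than `m` mismatches, or inside a construct-internal blacklist
(e.g. an endogenous gene fragment carried on the vector), are discarded. With
multiple constructs only the single globally best hit per clip is kept, so
one clip can never seed two sites.

**3. Junction reconstruction and evidence scoring
(`reconstruct_junctions`, `build_candidates`, `score_candidate`).** The clip
side fixes the junction: a right clip means reference-then-T-DNA along the +
strand (config **R**, junction = last aligned base), a left clip the reverse
(config **L**, junction = first aligned base). The construct hit strand gives
the insertion orientation. Chimeric reads from **all replicates** are merged
and clustered by (chromosome, config); within a cluster the read with the
deepest junction coverage — maximal `min(genome_seg_len, tdna_seg_len)` — is
the *reference read*, and every other member falls into exactly one group:

| group | evidence | weight |
|---|---|---|
| G1 | same junction, different genome/T-DNA split ratio | 700 |
| G2 | same junction, sequence one base from the reference | 300 |
| G3 | identical sequence from a different biological replicate | 300 |
| G4 | junction within `w` (default 10 bp) but not identical | 1 |
| G5 | discordant pair: genomic anchor near and facing the junction, mate on the construct | 1 |

The confidence score is the weighted sum over supporters; the reference read
contributes nothing. A candidate passes at `score >= threshold` (default
1000), so the minimal passing configuration is three chimeric reads: the
reference, one G1 (700) and one further G1–G3 supporter (>= 300). G1 carries
the most weight because independent fragments crossing the same junction at
different offsets are hard to produce by artifact; G4/G5 are nearly neutral
tie-breaker evidence. The discordant stage is off by default — it adds little
at weight 1 and costs a pass over all pairs; a higher threshold (e.g. 2000)
can be configured for noisier material.

**4. Calling and reporting (`call_tis`, `run_pipeline`).** Candidates in
user-supplied blacklist regions (BED) are removed before reporting; passing
calls are annotated with overlapping GFF3 gene features and written as TSV
(all candidates with status), BED6 (passing calls; BED score capped at 1000,
the true score stays in the TSV) and an RPKM bedGraph coverage track
(`reads_in_bin / ((bin_width/1000) * (total_mapped/1e6))`). The R and L
flanks of one physical insertion are reported as two rows — they are
independent pieces of evidence with their own supporters — and can be paired
by coordinate (R at the base before the insertion, L immediately after).

## Coordinate and tie-break conventions

Everything internal is 1-based closed (SAM convention); BED and bedGraph
outputs are 0-based half-open. The junction is a single deterministic base:
the last aligned base for config R, the first for config L. Clip-length and
matched-length thresholds are inclusive (`>= l1`, `>= l2`); "close to a
border" is strictly `< d`; the mismatch rule keeps `mismatches <= m`; the
poly(N) rule excludes records at `>= 0.8` N-fraction of the genomic portion.
A score exactly at the threshold passes. Reference-read ties are broken by
lexicographic read id; equal-scoring construct hits keep the
lexicographically first construct id (logged). These choices make every stage
deterministic, which is what lets the pipeline guarantee byte-identical
output for any shard/thread count (work is split by replicate and chromosome
and merged in canonical order).

## What the simulator emulates — and what it does not

`simulate_reference_and_tdna`, `plant_insertions` and `simulate_reads`
generate a uniform-composition genome, non-overlapping expressed intervals,
and a construct; insertions (with optional border truncation and either
orientation) are planted between two bases, and reads are sampled uniformly
from the expressed intervals of the mutated genome with i.i.d. substitution
errors. Alignments are derived from the known truth, not from running an
aligner: junction-spanning reads get a soft clip exactly at the breakpoint.
The defaults used throughout the test suite are a 100-kb genome, ten 2-kb
expressed intervals, a 2-kb construct, 150-bp single-end reads at depth
30–40, two replicates, and zero substitution errors for the recovery
fixtures — enough coverage that each flank receives several qualifying
junction reads, which is the regime the method is designed for.

The simulator deliberately omits splicing, indels, quality-score structure,
coverage bias, trans-splicing artifacts and chromosomal rearrangements, and
its truth-derived alignments have no mapping ambiguity. Passing the recovery
tests therefore demonstrates the correctness of the pipeline's bookkeeping
(coordinates, orientation, clustering, scoring, filtering), not robustness to
aligner idiosyncrasies or biological artifacts of real RNA-seq.

## Design choices made where the design was open

* **Reference-read weight.** The reference read scores zero; weights apply to
  supporters only. This is forced by the minimal three-read configuration:
  reference + G1 + G3 = 700 + 300 = 1000, exactly at the default threshold.
* **Local alignment definition.** Substitutions only, no gaps; windows start
  and end on a match. Small junction indels do occur in real data; under this
  model they shorten the matched window rather than being bridged. This keeps
  the search space exactly enumerable, and the implementation is verified
  against an exhaustive all-offset, both-strand scorer on randomized
  instances. A gapped mode was considered and rejected: within a one-mismatch
  budget it changes few decisions and removes the exact-oracle guarantee.
* **Clustering window `w` = 10 bp.** Junction wobble from sequencing errors
  and ragged local alignment is within a few bases; 10 bp groups those
  without merging genuinely distinct nearby insertions.
* **Duplicate key.** Per replicate, on the full read sequence plus span and
  clip side (not the clip alone) — see stage 1.
* **Evaluation matching.** Calls match truth entries greedily by nearest
  distance, one-to-one, within a tolerance (default 100 bp; the recovery
  tests use 0 because truth-derived alignments are exact).
* **Flanks are not merged.** Whether both flanks of one insertion should pool
  their evidence is genuinely ambiguous (one flank may fall in untranscribed
  sequence); keeping them separate is conservative and loses nothing, since
  either flank can pass on its own.

## Degenerate inputs and failure modes

Malformed CIGARs or records without sequence are skipped with a warning,
never aborting a stream. An empty construct sequence, an unreadable blacklist
or annotation file, and a zero-replicate configuration are immediate errors.
Zero parsable alignments produce an empty report with a warning and exit
status 0. Single-end input to the discordant stage returns an empty result
with a message.

## Known limitations

* Read length dominates performance. A 150-bp read can place a junction
  anywhere in an ~83-bp window and still satisfy both the genome-anchor
  fraction (0.33 × 150 → 50 bases) and the 18-bp clip minimum. A 50-bp read
  under the default `r` = 0.67 would need ≥ 34 genome-aligned bases *plus* an
  18-bp clip — more than the read holds — so at 50 bp no junction read
  qualifies at all unless `r` is lowered explicitly.
* Insertions in untranscribed regions are invisible to RNA-seq input by
  construction; use WGS mode (`mode = "wgs"`, mapq floor 30) on genomic data.
* Mis-splicing around an insertion can create several apparent junctions for
  one physical event; these are reported as-is, not merged.
* The ungapped aligner understates support when a junction carries an indel
  within the clipped segment.
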