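---
title: "Validating fusion transcripts in matched WGS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fusion transcripts in matched WGS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseval)
```

## The problem

Fusion transcripts called from tumor RNA-Seq are plagued by false positives:
reverse-transcription artifacts, read-through transcription and misalignment
all produce chimeric reads without any underlying genomic rearrangement. When
matched whole-genome sequencing (WGS) is available, a genuine fusion should
leave two independent DNA-level footprints: read pairs whose mates map to the
two partner loci at an impossible distance or on different chromosomes
(*discordant pairs*), and reads that run across the DNA breakpoint itself,
aligning partly to one partner with the remainder *soft-clipped* and matching
the other partner.

`fuseval` validates a table of candidate fusions against an indexed WGS BAM.
Because the RNA junction pins down where in each gene the breakpoint must lie,
the search can be restricted to a small region per partner, which keeps the
approach both fast and sensitive compared to genome-wide structural-variant
callers.

## Search-region geometry

DNA evidence for a fusion lies, in transcriptional direction, *downstream* of
the junction in the 5' partner and *upstream* of it in the 3' partner: the
transcribed part of each partner is retained in the fusion, so the DNA break
must fall between the junction and the far gene boundary. The search region
for a 5' partner therefore spans junction → gene end, and for a 3' partner
gene start → junction, each padded by 500 bp on the junction side and 2 kb
beyond the gene boundary. All coordinates are genomic, 1-based inclusive; for
minus-strand genes the transcriptional start/end swap genomic sides, which
`compute_search_region()` handles via the role-by-strand table below.

The same table determines on which genomic side of the junction the
breakpoint (and hence the soft clip of a junction-spanning read) is expected:

| partner role | strand | breakpoint / clip side |
|--------------|--------|------------------------|
| 5'           | +      | right                  |
| 5'           | −      | left                   |
| 3'           | +      | left                   |
| 3'           | −      | right                  |

This table is encoded explicitly (`breakpoint_side()`, `expected_clip_side()`)
rather than left implicit in arithmetic, and the test suite verifies against
simulation that junction-spanning reads carry their clips on the predicted
side for all four role–strand combinations.

Input tables normally ship precomputed search bounds (the 13-column schema),
which are trusted verbatim; `compute_search_region()` exists for users who
start from gene annotation instead. Regions are clamped to `[1, contig
length]` using the BAM header so padding near contig edges cannot produce
invalid queries.

## Discordant-pair extraction and filters

For each fusion, reads overlapping the 5' region whose mate starts inside the
3' region (and vice versa) are fetched by index query; each pair is counted
once. Mate membership is tested on the mate's leftmost coordinate, which is
available on the anchor record without fetching the mate — the reproducible,
index-friendly reading of "the mate maps to the other region". Pairs are then
filtered:

* PCR/optical duplicates are discarded (flag 0x400);
* mapping quality 0 — multimapping — discards the pair;
* secondary and supplementary alignments are excluded, so each fragment is
  counted exactly once;
* intrachromosomal pairs whose *outer alignment span* is ≤ 4 kb are
  discarded. Adjacent genes can have overlapping search regions, and
  ordinary-size fragments would otherwise masquerade as support. The span is
  computed from the two alignments' outer coordinates, not the TLEN field,
  which aligners fill inconsistently for discordant pairs. The 4 kb default
  reflects typical WGS fragment-size distributions and is user-tunable
  (`min_fragment`).

If either mate fails, the pair is dropped. A per-fusion log records counts
discarded at each stage. The test suite holds the indexed extraction to exact
agreement with a brute-force scan of every record in the file applying the
same predicates.

## Breakpoint search and soft-clip realignment

A genomic breakpoint can lie at most about one fragment length from any
discordant read, so a search region is built around each discordant mate:
500 bp of padding toward the expected breakpoint side and 50 bp the other
way. Overlapping or abutting regions for the same fusion are merged
(coordinate union) so reads are fetched once; merged regions keep the union
of contributing pair ids, letting every breakpoint call be traced back to
specific discordant pairs.

From these regions, reads with a soft clip on the expected side are
extracted, excluding duplicates, MAPQ 0 and secondary/supplementary records
as before (the same unique-fragment reasoning applies). Clips shorter than
6 bp, or with mean Phred quality ≤ 15 (a mean of exactly 15.0 fails), are
discarded; "mean" is the arithmetic mean of the clipped bases' scores. Hard
clips are ignored — they carry no sequence. The coordinate of the aligned
base adjacent to the clip (`anchor_breakpoint`) is the breakpoint candidate:
the rightmost aligned base for right-side clips, the leftmost for left-side
clips.

Each surviving clip is realigned into the partner's breakpoint search-region
sequence with a Smith–Waterman local aligner (match +2, mismatch −3, gap
opening 5, gap extension 2; a gap of length *L* costs 5 + 2*L*), tried in
both forward and reverse-complement orientation; the better score wins and
ties go to forward. Both orientations are always tried rather than derived
from strand annotation — robust to unannotated inversion geometry — and the
observed orientation is reported for QC (when partner strands match,
passing alignments should be forward; when they differ, reverse-complement).
An alignment is accepted when ≥ 90% of the clip aligns and ≥ 90% of aligned
columns match (`clip_coverage`, `clip_identity`); these acceptance thresholds
are configuration, not biology, and both are exposed. Scores are verified in
the test suite against an exhaustive dynamic-programming oracle.

Accepted candidates are grouped per partner by exact anchor coordinate —
soft-clip boundaries from a single aligner are reproducible, so no fuzz
window is applied by default, though `breakpoint_merge_window` exposes one
(the reported coordinate is then the most-supported one in the cluster, ties
to the smallest). Support is the number of *distinct* read names.

## Reporting

Per fusion, the summary flags are:

* `validated` — at least one discordant pair;
* `breakpoint_found` — a breakpoint call in either partner;
* `high_support` — ≥ 5 discordant pairs and/or an identified breakpoint.

Breakpoints are only searched near discordant reads, so `breakpoint_found`
implies `validated`. Every input fusion gets exactly one summary row; zero
support is a result, not an error.

## The simulator: what it emulates and what it does not

`simulate_fusion_dataset()` builds a uniform-random reference genome (default
two 50 kb contigs), a fused allele joining the 5' partner's sequence up to
its breakpoint with the 3' partner's sequence from its breakpoint on
(segments reverse-complemented for minus-strand partners), and a paired-end
read set drawn from a normal/fused mixture: normal fragment lengths (default
400 ± 50 bp), 100 bp reads, uniform substitution errors (default 0.1%), a
configurable duplicate fraction, MAPQ 60 throughout. Reads are written
directly as aligned records — junction-spanning reads receive the exact
soft-clip CIGAR their placement implies — then coordinate-sorted and indexed.
A truth manifest records each fragment's provenance and which fragments span
the junction with mates anchored in different partners.

Defaults model a clonal heterozygous fusion (`fusion_allele_fraction = 0.5`)
at 30× coverage. Writing pre-aligned records keeps the tests hermetic and
deterministic, but it also means passing tests say nothing about aligner
behavior on real data: ambiguous placement near repeats, indel errors,
chimeric artifacts, clipped-base miscalls and reference bias are all outside
the model, as are GC bias and non-uniform coverage. What the simulation does
establish is that the region geometry, filter cascade, clip bookkeeping and
breakpoint arithmetic are exact: on simulated data every reported breakpoint
coordinate equals a planted one.

The skim-depth scenario uses 0.02× coverage. The expected number of
junction-spanning fragments is approximately
`fraction × n_fragments × (fragment_mean − read_length) / fused_length`,
≈ 0.03 per replicate at these settings — the regime of sub-1× skim WGS, where
discordant-pair validation has essentially no physical coverage of the
junction to work with and the pipeline should (and does) come up empty.

## Numerical and design choices

* **Coordinates** are 1-based inclusive in all I/O; any half-open internal
  representation (BED input, IRanges internals) converts at the boundary.
* **Thousands separators** and the typographic minus are accepted on input,
  never emitted.
* **Span boundary**: "4 kb or smaller" is read literally — a span of exactly
  4000 fails, 4001 passes. 4 kb means 4000, not 4096.
* **Quality boundary**: "15 or less" is a strict reject at ≤ 15.0.
* **Abutting breakpoint regions** (end + 1 = start) are merged: they would
  fetch adjacent reads anyway, and merging simplifies bookkeeping.
* **Tie-breaks**: equal-scoring alignment orientations resolve to forward;
  equal-support coordinates in a merge window resolve to the smallest
  coordinate; the anchor side of a read split exactly in half by the
  junction resolves to the 5' block in the simulator.
* **Problem sizes** in the test and acceptance runs use 10–24 kb contigs and
  20 replicates per stochastic property — large enough that binomial
  fluctuations are far from the asserted bounds, small enough to keep the
  suite quick.

## Limitations

* One junction per fusion: no reciprocal-junction search, no contig
  assembly, no microhomology annotation at the breakpoint.
* Validation evidence is bounded by WGS depth; below ~1× physical coverage
  of the junction there is nothing to find (see the skim-depth scenario).
* The clip realigner reports the first-best locus; a clip matching equally
  well at two loci within the partner region is not disambiguated.
* No parser for specific fusion callers' native formats — callers' output
  must be converted to the 13-column table first.
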