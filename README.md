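# fuseval

Validation of RNA-Seq-detected fusion transcripts in matched whole-genome
sequencing (WGS) data.

## What it does, and for whom

Fusion transcripts called from tumor RNA-Seq (FusionCatcher, Arriba, STAR-
Fusion, …) carry a substantial false-positive burden. When matched WGS exists,
a real fusion leaves two DNA footprints: **discordant read pairs** bridging
the two partner loci, and **soft-clipped reads** crossing the genomic
breakpoint whose clipped tail matches the other partner. `fuseval` checks a
table of candidate fusions for both, and reports the breakpoint coordinates
it can pin down — for cancer genomicists who want DNA-level confirmation of
RNA-level fusion calls without running a genome-wide structural-variant
caller.

Because the RNA junction constrains where the DNA break can lie, only a small
region per partner needs searching: for the 5' partner the region runs from
the fusion junction to the end of the gene, for the 3' partner from the start
of the gene to the junction (in transcriptional direction; minus-strand genes
swap genomic sides), padded 500 bp past the junction and 2 kb past the gene
boundary. Pairs linking the two regions are kept if neither mate is a
duplicate, multimapping (MAPQ 0) or secondary, and — for intrachromosomal
candidates — the outer fragment span exceeds 4 kb. Around each discordant
read, soft clips ≥ 6 bp with mean base quality > 15 on the strand-determined
side are realigned (Smith–Waterman, both orientations) into the partner
region; clips aligning at ≥ 90% identity and coverage support a breakpoint
call at the clip's anchor coordinate, counted in distinct reads.

A fusion is `validated` with ≥ 1 discordant pair, and `high_support` with
≥ 5 pairs and/or an identified genomic breakpoint.

## Worked example

The bundled simulator builds a complete dataset — reference FASTA, aligned
BAM, fusion table, truth manifest — so the example is fully self-contained:

```r
library(fuseval)

cfg <- sim_config(seed = 11, chrom_lengths = c(chrA = 20000L, chrB = 20000L),
                  breakpoint_5p = 12000L, breakpoint_3p = 7000L,
                  strand_5p = "+", strand_3p = "-", coverage = 30)
ds <- simulate_fusion_dataset(cfg, "demo")
summary <- run_pipeline(ds$fusion_table, ds$fasta, "demo/out")
as.data.frame(summary)
#>   fusion_id  sample_id n_discordant_pairs validated breakpoint_found high_support
#> 1  fusion_1 sim_sample                 41      TRUE             TRUE         TRUE

attr(summary, "breakpoints")[, c("partner_role", "chrom", "coordinate",
                                 "n_support_reads", "orientations")]
#>   partner_role chrom coordinate n_support_reads          orientations
#> 1  three_prime  chrB       7000              14 reverse_complement:14
#> 2   five_prime  chrA      12000               8  reverse_complement:8
```

41 read pairs link the two search regions (the truth manifest plants exactly
41 clean junction-spanning fragments), and soft-clip realignment recovers
both planted breakpoints — chrA:12000 and chrB:7000 — exactly. The clips
align in reverse-complement orientation because the partners sit on opposite
strands. `demo/out/` holds the pair, breakpoint and summary tables as TSV,
plus a per-stage filter log.

Real data runs the same way: a 13-column tab-separated fusion table
(`fusion_id`, `sample_id`, `path`, and per-partner
chromosome/strand/junction/search bounds; thousands separators tolerated),
an indexed reference FASTA, and indexed BAMs referenced by the table's
`path` column:

```r
run_pipeline("fusions.tsv", "genome.fa", "results/")
```

Every threshold is a `run_config()` argument, and a command-line wrapper is
available at `inst/cli/fuseval.R` (`validate` and `simulate` subcommands).

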