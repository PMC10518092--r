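# Fixture builders: a hand-rolled SAM writer for crafted alignment records,
# a read-record constructor for pure predicate tests, and small simulator
# presets sized for fast test runs.

# records: list of lists with fields qname, flag, chrom, pos, mapq, cigar,
# rnext, pnext, tlen, seq, qual (seq/qual default to match query width).
write_mini_bam <- function(records, chrom_lengths,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  qwidth <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    sum(vapply(ops, function(o) {
      if (grepl("[MIS=X]", o)) as.integer(sub("[A-Z=]", "", o)) else 0L
    }, integer(1)))
  }
  lines <- vapply(records, function(r) {
    qw <- qwidth(r$cigar)
    seq <- if (is.null(r$seq)) strrep("A", qw) else r$seq
    qual <- if (is.null(r$qual)) strrep("I", qw) else r$qual
    paste(r$qname, r$flag, r$chrom, r$pos,
          if (is.null(r$mapq)) 60L else r$mapq, r$cigar,
          if (is.null(r$rnext)) "*" else r$rnext,
          if (is.null(r$pnext)) 0L else r$pnext,
          if (is.null(r$tlen)) 0L else r$tlen,
          seq, qual, sep = "\t")
  }, character(1))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  sam <- file.path(dir, "mini.sam")
  writeLines(c(header, lines), sam)
  tmp <- Rsamtools::asBam(sam, file.path(dir, "mini_unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(tmp, file.path(dir, "mini"))
  Rsamtools::indexBam(bam)
  bam
}

# Minimal read record for pair_passes_filters().
make_read <- function(chrom = "chr1", pos = 1000L, aln_end = pos + 99L,
                      mapq = 60L, is_dup = FALSE, is_secondary = FALSE,
                      is_supplementary = FALSE) {
  list(chrom = chrom, pos = as.integer(pos), aln_end = as.integer(aln_end),
       mapq = as.integer(mapq), is_dup = is_dup, is_secondary = is_secondary,
       is_supplementary = is_supplementary)
}

# Small, fast simulation preset: two 10 kb contigs, breakpoints mid-contig.
small_sim_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed,
                   chrom_lengths = c(chrA = 10000L, chrB = 10000L),
                   breakpoint_5p = 5000L, breakpoint_3p = 5000L,
                   coverage = 20)
  do.call(sim_config, utils::modifyList(defaults, args))
}

sim_dataset <- function(config) {
  simulate_fusion_dataset(config, withr::local_tempdir(.local_envir = parent.frame()))
}
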