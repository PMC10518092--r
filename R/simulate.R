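#' @title Paired-end WGS fusion simulator
#' @description Generate a synthetic reference genome, a fused allele with
#'   known DNA breakpoints, and a coordinate-sorted, indexed BAM of
#'   paired-end reads drawn from a mixture of the normal and fused alleles,
#'   together with a per-fragment truth manifest. Reads are written directly
#'   as aligned records (junction-spanning reads get the correct soft-clip
#'   CIGARs), so tests are hermetic and deterministic.
#' @name simfusion
NULL

#' Simulation configuration
#'
#' @param seed integer seed driving all randomness.
#' @param chrom_lengths named integer vector of contig lengths (default two
#'   50 kb contigs).
#' @param chrom_5p,chrom_3p contigs carrying the two fusion partners
#'   (defaults: first and second contig; set both to the same name for an
#'   intrachromosomal fusion).
#' @param breakpoint_5p,breakpoint_3p planted DNA breakpoint coordinates
#'   (1-based; the 5' partner contributes its sequence up to
#'   `breakpoint_5p`, the 3' partner from `breakpoint_3p` on, in
#'   transcriptional direction).
#' @param strand_5p,strand_3p partner strands.
#' @param fusion_allele_fraction fraction of fragments drawn from the fused
#'   allele (default 0.5, a heterozygous clonal event).
#' @param coverage mean base coverage of the genome (default 30).
#' @param read_length read length in bp (default 100).
#' @param fragment_mean,fragment_sd normal fragment-length distribution
#'   (defaults 400 and 50 bp).
#' @param base_error_rate uniform substitution error rate (default 0.001).
#' @param duplicate_fraction fraction of fragments flagged as PCR/optical
#'   duplicates (default 0.02).
#' @param gene_halfwidth half-width of the synthetic gene span placed around
#'   each breakpoint when emitting the fusion table (default 5000 bp).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrA = 50000L, chrB = 50000L),
                       chrom_5p = names(chrom_lengths)[1L],
                       chrom_3p = names(chrom_lengths)[min(2L, length(chrom_lengths))],
                       breakpoint_5p = 25000L, breakpoint_3p = 25000L,
                       strand_5p = "+", strand_3p = "+",
                       fusion_allele_fraction = 0.5,
                       coverage = 30, read_length = 100L,
                       fragment_mean = 400, fragment_sd = 50,
                       base_error_rate = 0.001,
                       duplicate_fraction = 0.02,
                       gene_halfwidth = 5000L) {
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = setNames(as.integer(chrom_lengths),
                                       names(chrom_lengths)),
              chrom_5p = chrom_5p, chrom_3p = chrom_3p,
              breakpoint_5p = as.integer(breakpoint_5p),
              breakpoint_3p = as.integer(breakpoint_3p),
              strand_5p = normalize_strand(strand_5p),
              strand_3p = normalize_strand(strand_3p),
              fusion_allele_fraction = fusion_allele_fraction,
              coverage = coverage, read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              base_error_rate = base_error_rate,
              duplicate_fraction = duplicate_fraction,
              gene_halfwidth = as.integer(gene_halfwidth))
  stopifnot(length(cfg$chrom_lengths) >= 1L,
            !is.null(names(cfg$chrom_lengths)),
            cfg$chrom_5p %in% names(cfg$chrom_lengths),
            cfg$chrom_3p %in% names(cfg$chrom_lengths),
            cfg$breakpoint_5p >= 1L,
            cfg$breakpoint_5p <= cfg$chrom_lengths[[cfg$chrom_5p]],
            cfg$breakpoint_3p >= 1L,
            cfg$breakpoint_3p <= cfg$chrom_lengths[[cfg$chrom_3p]],
            cfg$fusion_allele_fraction >= 0, cfg$fusion_allele_fraction <= 1,
            cfg$base_error_rate >= 0, cfg$base_error_rate <= 1,
            cfg$duplicate_fraction >= 0, cfg$duplicate_fraction <= 1,
            cfg$coverage >= 0, cfg$read_length >= 20L)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference genome
#'
#' Seeded i.i.d. uniform bases per contig; byte-identical FASTA (plus `.fai`
#' index) for a given seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `fasta` (path) and `seqs` (`DNAStringSet`).
#' @export
simulate_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  seqs <- Biostrings::DNAStringSet(
    vapply(config$chrom_lengths, random_dna, character(1)))
  names(seqs) <- names(config$chrom_lengths)
  fasta <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)
  list(fasta = fasta, seqs = seqs)
}

#' Construct the fused allele and its junction map
#'
#' The fused allele is the 5' partner's transcribed sequence up to its
#' breakpoint joined to the 3' partner's sequence from its breakpoint on:
#' plus-strand segments are taken forward, minus-strand segments
#' reverse-complemented. The junction map records, for every fused-allele
#' position, its source contig, 1-based coordinate and strand.
#'
#' @param ref_seqs `DNAStringSet` of reference contigs.
#' @param config a [sim_config()].
#' @return list with `seq` (character), `map` (`data.frame` chrom/pos/strand
#'   per fused position), `junction_index` (last fused position from the 5'
#'   partner).
#' @export
simulate_fused_allele <- function(ref_seqs, config) {
  s5 <- ref_seqs[[config$chrom_5p]]
  s3 <- ref_seqs[[config$chrom_3p]]
  b5 <- config$breakpoint_5p
  b3 <- config$breakpoint_3p
  if (config$strand_5p == "+") {
    seg5 <- as.character(Biostrings::subseq(s5, 1L, b5))
    pos5 <- seq_len(b5)
  } else {
    seg5 <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(s5, b5, length(s5))))
    pos5 <- seq(length(s5), b5)
  }
  if (config$strand_3p == "+") {
    seg3 <- as.character(Biostrings::subseq(s3, b3, length(s3)))
    pos3 <- seq(b3, length(s3))
  } else {
    seg3 <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(s3, 1L, b3)))
    pos3 <- seq(b3, 1L)
  }
  map <- data.frame(
    chrom = c(rep(config$chrom_5p, length(pos5)),
              rep(config$chrom_3p, length(pos3))),
    pos = c(pos5, pos3),
    strand = c(rep(config$strand_5p, length(pos5)),
               rep(config$strand_3p, length(pos3))),
    stringsAsFactors = FALSE
  )
  list(seq = paste0(seg5, seg3), map = map, junction_index = length(pos5))
}

# Uniform substitution errors on a character vector of sequences.
apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- sample.int(length(s), n_err[i])
    s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1L),
                    character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# One aligned record for a read covering fused-allele interval [a, b].
# `physical_forward` is TRUE when the sequencer read the fused-allele
# forward strand (mate 1 of an FR pair at the fragment's left end).
fused_read_record <- function(a, b, fused_seq, map, junction_index,
                              physical_forward) {
  J <- junction_index
  blocks <- list()
  if (a <= min(b, J)) blocks[[length(blocks) + 1L]] <- c(a, min(b, J))
  if (max(a, J + 1L) <= b) blocks[[length(blocks) + 1L]] <- c(max(a, J + 1L), b)
  lens <- vapply(blocks, function(x) x[2L] - x[1L] + 1L, integer(1))
  anchor <- blocks[[which.max(lens)]]  # ties -> first (5' side)
  ba <- anchor[1L]; bb <- anchor[2L]
  st <- map$strand[ba]
  chrom <- map$chrom[ba]
  ref_start <- min(map$pos[ba], map$pos[bb])
  M <- bb - ba + 1L
  lclip <- ba - a
  rclip <- b - bb
  Fseq <- substr(fused_seq, a, b)
  if (st == "+") {
    seq_out <- Fseq
    cigar <- paste0(if (lclip > 0L) paste0(lclip, "S") else "",
                    M, "M",
                    if (rclip > 0L) paste0(rclip, "S") else "")
    reverse <- !physical_forward
    clip_side <- if (rclip > 0L) "right" else if (lclip > 0L) "left" else NA_character_
  } else {
    seq_out <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(Fseq)))
    cigar <- paste0(if (rclip > 0L) paste0(rclip, "S") else "",
                    M, "M",
                    if (lclip > 0L) paste0(lclip, "S") else "")
    reverse <- physical_forward
    clip_side <- if (lclip > 0L) "right" else if (rclip > 0L) "left" else NA_character_
  }
  list(chrom = chrom, pos = ref_start, cigar = cigar, seq = seq_out,
       reverse = reverse, aln_end = ref_start + M - 1L,
       partner = if (ba <= J) "five_prime" else "three_prime",
       crosses = length(blocks) == 2L, clip_side = clip_side,
       clip_len = max(lclip, rclip))
}

#' Simulate an aligned paired-end read set
#'
#' Fragments are drawn with normal(`fragment_mean`, `fragment_sd`) lengths
#' from a mixture of the normal contigs and the fused allele
#' (`fusion_allele_fraction`). Reads are placed at their true reference
#' coordinates; reads crossing the junction are soft-clipped on the portion
#' continuing into the other partner. A `duplicate_fraction` of fragments is
#' flagged as duplicates; MAPQ is 60 throughout. The BAM is coordinate
#' sorted and indexed.
#'
#' @param ref_seqs `DNAStringSet` of reference contigs.
#' @param fused result of [simulate_fused_allele()] (may be `NULL` when
#'   `fusion_allele_fraction` is 0).
#' @param config a [sim_config()].
#' @param out_prefix path prefix for the BAM (writes `<prefix>.bam` +
#'   index).
#' @return list with `bam` (path) and `truth`: planted breakpoints, a
#'   per-fragment provenance table, and the count of clean junction-spanning
#'   (discordant) fragments.
#' @export
simulate_reads <- function(ref_seqs, fused, config, out_prefix) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  G <- sum(config$chrom_lengths)
  n_frag <- max(0L, as.integer(round(config$coverage * G / (2 * rl))))
  frac <- if (is.null(fused)) 0 else config$fusion_allele_fraction

  sources <- c(names(config$chrom_lengths),
               if (!is.null(fused)) "__fused__")
  src_len <- c(config$chrom_lengths,
               if (!is.null(fused)) nchar(fused$seq))
  names(src_len) <- sources
  probs <- c((1 - frac) * config$chrom_lengths / G,
             if (!is.null(fused)) frac)
  src <- if (n_frag > 0L) {
    sample(sources, n_frag, replace = TRUE, prob = probs)
  } else character(0)
  flen <- pmin(pmax(as.integer(round(stats::rnorm(
    n_frag, config$fragment_mean, config$fragment_sd))), rl),
    as.integer(src_len[src]))
  fstart <- as.integer(floor(stats::runif(n_frag) *
                               (src_len[src] - flen + 1))) + 1L
  is_dup <- stats::runif(n_frag) < config$duplicate_fraction
  qual_val <- sample(30:40, n_frag, replace = TRUE)

  qname <- sprintf("frag%06d", seq_len(n_frag))
  rec_chrom <- character(2L * n_frag); rec_pos <- integer(2L * n_frag)
  rec_flag <- integer(2L * n_frag); rec_cigar <- character(2L * n_frag)
  rec_rnext <- character(2L * n_frag); rec_pnext <- integer(2L * n_frag)
  rec_tlen <- integer(2L * n_frag); rec_seq <- character(2L * n_frag)
  na_chr <- rep(NA_character_, n_frag)
  tr <- list(discordant = logical(n_frag),
             r1_chrom = na_chr, r1_pos = integer(n_frag),
             r1_clip_side = na_chr, r1_clip_len = integer(n_frag),
             r1_partner = na_chr,
             r2_chrom = na_chr, r2_pos = integer(n_frag),
             r2_clip_side = na_chr, r2_clip_len = integer(n_frag),
             r2_partner = na_chr)

  chrom_chars <- as.character(ref_seqs)

  for (i in seq_len(n_frag)) {
    s <- fstart[i]; l <- flen[i]
    a1 <- s; b1 <- s + rl - 1L
    a2 <- s + l - rl; b2 <- s + l - 1L
    if (src[i] == "__fused__") {
      rec1 <- fused_read_record(a1, b1, fused$seq, fused$map,
                                fused$junction_index, TRUE)
      rec2 <- fused_read_record(a2, b2, fused$seq, fused$map,
                                fused$junction_index, FALSE)
      discordant <- rec1$partner != rec2$partner
      proper <- !rec1$crosses && !rec2$crosses && !discordant
    } else {
      S <- chrom_chars[[src[i]]]
      rec1 <- list(chrom = src[i], pos = a1, cigar = paste0(rl, "M"),
                   seq = substr(S, a1, b1), reverse = FALSE,
                   aln_end = b1, partner = NA_character_, crosses = FALSE,
                   clip_side = NA_character_, clip_len = 0L)
      rec2 <- list(chrom = src[i], pos = a2, cigar = paste0(rl, "M"),
                   seq = substr(S, a2, b2), reverse = TRUE,
                   aln_end = b2, partner = NA_character_, crosses = FALSE,
                   clip_side = NA_character_, clip_len = 0L)
      discordant <- FALSE
      proper <- TRUE
    }
    same_chrom <- rec1$chrom == rec2$chrom
    tlen1 <- if (same_chrom) {
      sp <- max(rec1$aln_end, rec2$aln_end) - min(rec1$pos, rec2$pos) + 1L
      if (rec1$pos <= rec2$pos) sp else -sp
    } else 0L
    flag1 <- FLAG_PAIRED + FLAG_FIRST +
      (if (proper) FLAG_PROPER else 0L) +
      (if (rec1$reverse) FLAG_REVERSE else 0L) +
      (if (rec2$reverse) FLAG_MATE_REVERSE else 0L) +
      (if (is_dup[i]) FLAG_DUP else 0L)
    flag2 <- FLAG_PAIRED + FLAG_SECOND +
      (if (proper) FLAG_PROPER else 0L) +
      (if (rec2$reverse) FLAG_REVERSE else 0L) +
      (if (rec1$reverse) FLAG_MATE_REVERSE else 0L) +
      (if (is_dup[i]) FLAG_DUP else 0L)
    j1 <- 2L * i - 1L; j2 <- 2L * i
    rec_chrom[j1] <- rec1$chrom; rec_chrom[j2] <- rec2$chrom
    rec_pos[j1] <- rec1$pos; rec_pos[j2] <- rec2$pos
    rec_flag[j1] <- flag1; rec_flag[j2] <- flag2
    rec_cigar[j1] <- rec1$cigar; rec_cigar[j2] <- rec2$cigar
    rec_rnext[j1] <- if (same_chrom) "=" else rec2$chrom
    rec_rnext[j2] <- if (same_chrom) "=" else rec1$chrom
    rec_pnext[j1] <- rec2$pos; rec_pnext[j2] <- rec1$pos
    rec_tlen[j1] <- tlen1; rec_tlen[j2] <- -tlen1
    rec_seq[j1] <- rec1$seq; rec_seq[j2] <- rec2$seq
    tr$discordant[i] <- discordant
    tr$r1_chrom[i] <- rec1$chrom; tr$r1_pos[i] <- rec1$pos
    tr$r1_clip_side[i] <- rec1$clip_side; tr$r1_clip_len[i] <- rec1$clip_len
    tr$r1_partner[i] <- rec1$partner
    tr$r2_chrom[i] <- rec2$chrom; tr$r2_pos[i] <- rec2$pos
    tr$r2_clip_side[i] <- rec2$clip_side; tr$r2_clip_len[i] <- rec2$clip_len
    tr$r2_partner[i] <- rec2$partner
  }

  rec_seq <- apply_base_errors(rec_seq, config$base_error_rate)
  qual_chr <- if (n_frag > 0L) {
    strsplit(intToUtf8(qual_val + 33L), "", fixed = TRUE)[[1L]]
  } else character(0)
  qual_str <- strrep(qual_chr, rl)
  sam_lines <- if (n_frag > 0L) {
    paste(rep(qname, each = 2L), rec_flag, rec_chrom, rec_pos, 60L,
          rec_cigar, rec_rnext, rec_pnext, rec_tlen, rec_seq,
          rep(qual_str, each = 2L), sep = "\t")
  } else character(0)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(config$chrom_lengths),
                      config$chrom_lengths))
  sam_path <- paste0(out_prefix, ".sam")
  writeLines(c(header, sam_lines), sam_path)
  bam_tmp <- Rsamtools::asBam(sam_path, paste0(out_prefix, "_unsorted"),
                              overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam_tmp, out_prefix)
  Rsamtools::indexBam(bam)
  unlink(c(sam_path, bam_tmp))

  fragments <- data.frame(frag_id = qname, source = src, start = fstart,
                          length = flen, is_dup = is_dup,
                          as.data.frame(tr, stringsAsFactors = FALSE),
                          stringsAsFactors = FALSE)
  n_span <- if (n_frag > 0L) sum(fragments$discordant & !fragments$is_dup) else 0L
  truth <- list(
    breakpoints = list(
      five_prime = list(chrom = config$chrom_5p,
                        coordinate = config$breakpoint_5p,
                        strand = config$strand_5p),
      three_prime = list(chrom = config$chrom_3p,
                         coordinate = config$breakpoint_3p,
                         strand = config$strand_3p)),
    n_fragments = n_frag,
    n_fused_fragments = if (n_frag > 0L) sum(src == "__fused__") else 0L,
    n_spanning_clean = n_span,
    fragments = fragments
  )
  list(bam = bam, truth = truth)
}

#' Simulate a complete, ready-to-run fusion dataset
#'
#' Writes a reference FASTA (indexed), a sorted+indexed BAM, a fusion table
#' in the 13-column input schema, and a JSON truth manifest into `dir`. The
#' fusion-table junction coordinates are set at the planted DNA breakpoints
#' and the search bounds are derived with [compute_search_region()] from a
#' synthetic gene span of `gene_halfwidth` around each breakpoint.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list with paths (`fasta`, `bam`, `fusion_table`, `truth_json`),
#'   the fusion `table` itself, and the `truth` manifest.
#' @export
simulate_fusion_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config, dir)
  fused <- if (config$fusion_allele_fraction > 0) {
    simulate_fused_allele(ref$seqs, config)
  } else NULL
  sim <- simulate_reads(ref$seqs, fused, config, file.path(dir, "reads"))

  mk_region <- function(bp, chrom, strand, role) {
    len <- config$chrom_lengths[[chrom]]
    gb <- gene_bounds(chrom, max(1L, bp - config$gene_halfwidth),
                      min(len, bp + config$gene_halfwidth), strand)
    compute_search_region(bp, gb, role, chrom_length = len)
  }
  r5 <- mk_region(config$breakpoint_5p, config$chrom_5p, config$strand_5p,
                  "five_prime")
  r3 <- mk_region(config$breakpoint_3p, config$chrom_3p, config$strand_3p,
                  "three_prime")
  tab <- data.frame(
    fusion_id = "fusion_1", sample_id = "sim_sample", path = sim$bam,
    fiveprime_chr = config$chrom_5p, fiveprime_strand = config$strand_5p,
    fiveprime_junction = config$breakpoint_5p,
    fiveprime_search_start = r5$start, fiveprime_search_end = r5$end,
    threeprime_chr = config$chrom_3p, threeprime_strand = config$strand_3p,
    threeprime_junction = config$breakpoint_3p,
    threeprime_search_start = r3$start, threeprime_search_end = r3$end,
    stringsAsFactors = FALSE
  )
  table_path <- file.path(dir, "fusions.tsv")
  write_fusion_table(tab, table_path)
  truth_json <- file.path(dir, "truth.json")
  truth_out <- sim$truth
  truth_out$fragments <- NULL  # keep the manifest file small
  jsonlite::write_json(truth_out, truth_json, auto_unbox = TRUE, digits = NA)
  list(dir = dir, fasta = ref$fasta, bam = sim$bam,
       fusion_table = table_path, table = tab,
       truth = sim$truth, truth_json = truth_json, config = config)
}
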