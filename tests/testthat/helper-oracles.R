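# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the aligner oracle is a plain Gotoh dynamic
# program, the discordant oracle a linear scan over every BAM record, the
# merge oracle a pairwise interval-graph union.

# Affine-gap Smith-Waterman score by exhaustive dynamic programming.
# A gap of length L costs gap_open + L * gap_ext.
oracle_local_align_score <- function(query, target, match = 2, mismatch = -3,
                                     gap_open = 5, gap_ext = 2) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1L]]
  t <- strsplit(toupper(target), "", fixed = TRUE)[[1L]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)   # best score ending at (i, j)
  E <- matrix(NEG, n + 1L, m + 1L) # gap in query (consuming target)
  F <- matrix(NEG, n + 1L, m + 1L) # gap in target (consuming query)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (q[i - 1L] == t[j - 1L] && q[i - 1L] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_ext,
                     E[i, j - 1L] - gap_ext)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_ext,
                     F[i - 1L, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Full-file scan applying the discordant-pair predicates record by record:
# overlap of the 5' region, mate-start containment in the 3' region (and
# vice versa), duplicate / MAPQ-0 / secondary / supplementary exclusion, and
# the intrachromosomal outer-span cutoff. Returns the qualifying read names.
oracle_discordant_read_names <- function(bam, region5, region3,
                                         min_fragment = 4000L) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  flag <- as.integer(res$flag)
  mapped <- bitwAnd(flag, 0x4L) == 0L
  refw <- rep(0L, length(flag))
  refw[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    as.character(res$cigar)[mapped])
  df <- data.frame(qname = as.character(res$qname), flag = flag,
                   chrom = as.character(res$rname),
                   pos = as.integer(res$pos),
                   end = as.integer(res$pos) + refw - 1L,
                   mapq = as.integer(res$mapq),
                   mchrom = as.character(res$mrnm),
                   mpos = as.integer(res$mpos),
                   stringsAsFactors = FALSE)
  df <- df[mapped & bitwAnd(flag, 0x100L) == 0L &
             bitwAnd(flag, 0x800L) == 0L, , drop = FALSE]
  overlaps <- function(r, reg) {
    r$chrom == reg$chrom & r$pos <= reg$end & r$end >= reg$start
  }
  inside <- function(chrom, pos, reg) {
    chrom == reg$chrom & pos >= reg$start & pos <= reg$end
  }
  keep <- character(0)
  for (qn in unique(df$qname)) {
    rr <- df[df$qname == qn, , drop = FALSE]
    if (nrow(rr) != 2L) next
    a <- rr[1L, ]; b <- rr[2L, ]
    qualifies <- function(x, y) {
      overlaps(x, region5) & overlaps(y, region3) &
        (inside(x$mchrom, x$mpos, region3) | inside(y$mchrom, y$mpos, region5))
    }
    r5 <- NULL; r3 <- NULL
    if (qualifies(a, b)) { r5 <- a; r3 <- b }
    else if (qualifies(b, a)) { r5 <- b; r3 <- a }
    if (is.null(r5)) next
    if (any(bitwAnd(rr$flag, 0x400L) != 0L)) next   # duplicates
    if (any(rr$mapq == 0L | is.na(rr$mapq))) next   # multimapping
    if (r5$chrom == r3$chrom) {
      span <- max(r5$end, r3$end) - min(r5$pos, r3$pos) + 1L
      if (span <= min_fragment) next
    }
    keep <- c(keep, qn)
  }
  sort(keep)
}

# Pairwise-overlap connected-components interval merge (abutting intervals
# count as overlapping).
oracle_merge_intervals <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- start[i] <= end[j] + 1L & start[j] <= end[i] + 1L
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] < comp[i]) { comp[i] <- comp[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    data.frame(start = min(start[comp == cc]), end = max(end[comp == cc]))
  }))
  out[order(out$start), , drop = FALSE]
}
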