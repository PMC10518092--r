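#' @title Discordant read-pair extraction
#' @description Query an indexed BAM for read pairs linking the two partner
#'   search regions of a fusion and apply the pair-level filters.
#' @name discordant
NULL

# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

flag_bit <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

SCAN_WHAT <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize", "seq", "qual")

# Turn one scanBam result element into a read-record data.frame.
reads_to_df <- function(res) {
  n <- length(res$qname)
  cig <- as.character(res$cigar)
  refw <- integer(n)
  if (n > 0L) {
    ok <- !is.na(cig)
    refw[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[ok])
  }
  flag <- as.integer(res$flag)
  data.frame(
    read_name = as.character(res$qname),
    flag = flag,
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    aln_end = as.integer(res$pos) + refw - 1L,
    mapq = as.integer(res$mapq),
    cigar = cig,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    mate_chrom = as.character(res$mrnm),
    mate_pos = as.integer(res$mpos),
    tlen = as.integer(res$isize),
    is_dup = flag_bit(flag, FLAG_DUP),
    is_secondary = flag_bit(flag, FLAG_SECONDARY),
    is_supplementary = flag_bit(flag, FLAG_SUPPLEMENTARY),
    is_reverse = flag_bit(flag, FLAG_REVERSE),
    is_first = flag_bit(flag, FLAG_FIRST),
    is_mate_unmapped = flag_bit(flag, FLAG_MATE_UNMAPPED),
    stringsAsFactors = FALSE
  )
}

#' Fetch mapped reads overlapping a region
#'
#' Reads whose alignment overlaps `[start, end]` by at least one base,
#' unmapped records excluded. Coordinates are 1-based inclusive.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param chrom chromosome name (must exist in the BAM header).
#' @param start,end 1-based inclusive region bounds.
#' @return `data.frame` of read records (one row per alignment record).
#' @export
scan_region_reads <- function(bam, chrom, start, end) {
  check_bam(bam)
  sl <- bam_chrom_lengths(bam)
  if (!chrom %in% names(sl)) {
    stop("chromosome '", chrom, "' not present in BAM header of ", bam,
         call. = FALSE)
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  param <- Rsamtools::ScanBamParam(
    which = which, what = SCAN_WHAT,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  reads_to_df(res)
}

check_bam <- function(bam) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam, call. = FALSE)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)) &&
      !file.exists(paste0(bam, ".csi"))) {
    stop("BAM index (.bai/.csi) not found for: ", bam, call. = FALSE)
  }
  invisible(bam)
}

bam_chrom_lengths <- function(bam) {
  Rsamtools::scanBamHeader(bam)[[1L]]$targets
}

#' Candidate read pairs linking the two partner search regions
#'
#' A pair qualifies when one mate's alignment overlaps the 5' search region
#' and the other mate's leftmost coordinate lies within the 3' region's
#' bounds, or vice versa. Each qualifying pair is returned exactly once
#' (deduplicated by read name), oriented as (mate in 5' region, mate in 3'
#' region). No quality filtering happens here; see [pair_passes_filters()].
#'
#' @param bam indexed BAM path.
#' @param region5,region3 [search_region()] objects for the 5' and 3'
#'   partners.
#' @return `data.frame` with one row per pair: `read_name` plus `r5_*` and
#'   `r3_*` copies of the read-record fields, ordered by read name.
#' @export
fetch_candidate_pairs <- function(bam, region5, region3) {
  reads5 <- scan_region_reads(bam, region5$chrom, region5$start, region5$end)
  reads3 <- scan_region_reads(bam, region3$chrom, region3$start, region3$end)
  pair_up_candidates(reads5, reads3, region5, region3)
}

# Region-membership pairing shared by the indexed fetch and by brute-force
# scans: x must overlap region5, y must overlap region3, the two must be
# mates, and at least one direction of the "mate maps to the other region"
# predicate (on the mate's leftmost coordinate) must hold.
pair_up_candidates <- function(reads5, reads3, region5, region3) {
  empty <- empty_pair_df()
  if (nrow(reads5) == 0L || nrow(reads3) == 0L) return(empty)
  # exclude records that cannot form a primary pair twice
  m <- merge(reads5, reads3, by = "read_name",
             suffixes = c("_5", "_3"), sort = FALSE)
  if (nrow(m) == 0L) return(empty)
  mates <- m$is_first_5 != m$is_first_3 &
    m$mate_pos_5 == m$pos_3 & m$mate_pos_3 == m$pos_5 &
    m$mate_chrom_5 == m$chrom_3 & m$mate_chrom_3 == m$chrom_5
  mates[is.na(mates)] <- FALSE
  in3 <- m$pos_3 >= region3$start & m$pos_3 <= region3$end
  in5 <- m$pos_5 >= region5$start & m$pos_5 <= region5$end
  keep <- mates & (in3 | in5)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  # prefer primary alignments, then deduplicate by read name
  m <- m[order(m$read_name,
               m$is_secondary_5 | m$is_supplementary_5,
               m$is_secondary_3 | m$is_supplementary_3), , drop = FALSE]
  m <- m[!duplicated(m$read_name), , drop = FALSE]
  fields <- setdiff(names(reads5), "read_name")
  out <- data.frame(read_name = m$read_name, stringsAsFactors = FALSE)
  for (f in fields) {
    out[[paste0("r5_", f)]] <- m[[paste0(f, "_5")]]
    out[[paste0("r3_", f)]] <- m[[paste0(f, "_3")]]
  }
  rownames(out) <- NULL
  out
}

empty_pair_df <- function() {
  proto <- reads_to_df(list(qname = character(0), flag = integer(0),
                            rname = character(0), pos = integer(0),
                            mapq = integer(0), cigar = character(0),
                            mrnm = character(0), mpos = integer(0),
                            isize = integer(0), seq = character(0),
                            qual = character(0)))
  fields <- setdiff(names(proto), "read_name")
  out <- data.frame(read_name = character(0), stringsAsFactors = FALSE)
  for (f in fields) {
    out[[paste0("r5_", f)]] <- proto[[f]]
    out[[paste0("r3_", f)]] <- proto[[f]]
  }
  out
}

#' Pair-level quality filter
#'
#' True iff neither read is a PCR/optical duplicate, neither has mapping
#' quality 0 (multimapping), neither is a secondary or supplementary
#' alignment, both are mapped, and — when both map to the same chromosome —
#' the fragment spans more than `min_fragment` bases. The fragment span is
#' the outer alignment span, `max(aln_end) - min(pos) + 1`, not the TLEN
#' field, which is unreliable for discordant pairs.
#'
#' @param r1,r2 read records (one-row `data.frame` or named list with fields
#'   `chrom`, `pos`, `aln_end`, `mapq`, `is_dup`, `is_secondary`,
#'   `is_supplementary`).
#' @param min_fragment intrachromosomal span cutoff in bp (default 4000);
#'   spans of exactly `min_fragment` or less are discarded.
#' @return logical scalar.
#' @export
pair_passes_filters <- function(r1, r2, min_fragment = 4000L) {
  for (r in list(r1, r2)) {
    if (isTRUE(r$is_dup) || isTRUE(r$is_secondary) ||
        isTRUE(r$is_supplementary)) return(FALSE)
    if (is.na(r$mapq) || r$mapq == 0L) return(FALSE)
    if (is.na(r$pos)) return(FALSE)
  }
  if (identical(as.character(r1$chrom), as.character(r2$chrom))) {
    span <- max(r1$aln_end, r2$aln_end) - min(r1$pos, r2$pos) + 1L
    if (span <= min_fragment) return(FALSE)
  }
  TRUE
}

# Vectorized version over a candidate-pair data.frame; returns a logical
# keep vector plus per-stage discard counts for the run log.
pair_filter_vec <- function(pairs, min_fragment = 4000L) {
  dup <- pairs$r5_is_dup | pairs$r3_is_dup
  sec <- pairs$r5_is_secondary | pairs$r3_is_secondary |
    pairs$r5_is_supplementary | pairs$r3_is_supplementary
  mapq0 <- is.na(pairs$r5_mapq) | pairs$r5_mapq == 0L |
    is.na(pairs$r3_mapq) | pairs$r3_mapq == 0L
  same <- pairs$r5_chrom == pairs$r3_chrom
  span <- pmax(pairs$r5_aln_end, pairs$r3_aln_end) -
    pmin(pairs$r5_pos, pairs$r3_pos) + 1L
  short <- same & span <= min_fragment
  keep <- !dup & !sec & !mapq0 & !short
  list(keep = keep,
       span = ifelse(same, span, NA_integer_),
       counts = c(candidates = nrow(pairs),
                  dropped_duplicate = sum(dup),
                  dropped_secondary = sum(sec & !dup),
                  dropped_mapq0 = sum(mapq0 & !dup & !sec),
                  dropped_span = sum(short & !dup & !sec & !mapq0),
                  kept = sum(keep)))
}

#' Collect filtered discordant pairs for one fusion
#'
#' Runs [fetch_candidate_pairs()] and keeps pairs passing
#' [pair_passes_filters()]. Pair ids are `fusion_id:read_name`; rows are
#' ordered by read name so output is deterministic.
#'
#' @param bam indexed BAM path.
#' @param record fusion-table row (provides `fusion_id`, `sample_id`).
#' @param region5,region3 partner [search_region()]s.
#' @param min_fragment intrachromosomal span cutoff (default 4000).
#' @return `data.frame` of pairs with `pair_id`, `fusion_id`, `sample_id`,
#'   `fragment_span` (NA when interchromosomal) and the `r5_*`/`r3_*` record
#'   fields; per-stage filter counts in `attr(, "stage_counts")`.
#' @export
collect_discordant_pairs <- function(bam, record, region5, region3,
                                     min_fragment = 4000L) {
  cand <- fetch_candidate_pairs(bam, region5, region3)
  flt <- pair_filter_vec(cand, min_fragment = min_fragment)
  out <- cand[flt$keep, , drop = FALSE]
  out$fragment_span <- flt$span[flt$keep]
  out$fusion_id <- if (nrow(out)) record$fusion_id else character(0)
  out$sample_id <- if (nrow(out)) record$sample_id else character(0)
  out$pair_id <- if (nrow(out)) paste0(record$fusion_id, ":", out$read_name) else character(0)
  out <- out[order(out$read_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- flt$counts
  out
}
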