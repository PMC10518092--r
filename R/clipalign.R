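#' @title Soft-clip extraction and breakpoint calling
#' @description Extract soft-clipped read ends from breakpoint search
#'   regions, realign the clipped sequences into the partner region with a
#'   local aligner, and call genomic breakpoints with distinct-read support.
#' @name clipalign
NULL

#' Expected soft-clip side for a fusion partner
#'
#' A breakpoint-supporting read anchored in a fusion partner continues into
#' the other partner at the breakpoint, so its soft clip sits on the read
#' end facing the breakpoint; there is only one possible side per partner,
#' fixed by role and strand. The table coincides with [breakpoint_side()].
#'
#' @inheritParams breakpoint_side
#' @return `"left"` or `"right"`.
#' @export
expected_clip_side <- function(partner_role, strand) {
  breakpoint_side(partner_role, strand)
}

# Leading/trailing soft-clip lengths from CIGAR strings (hard clips are
# ignored: they carry no sequence). Vectorized.
cigar_clip_lengths <- function(cigar) {
  left <- rep(0L, length(cigar))
  right <- rep(0L, length(cigar))
  lpat <- "^(?:[0-9]+H)?([0-9]+)S"
  has <- grepl(lpat, cigar, perl = TRUE)
  left[has] <- as.integer(sub(paste0(lpat, ".*$"), "\\1", cigar[has],
                              perl = TRUE))
  rpat <- "([0-9]+)S(?:[0-9]+H)?$"
  has <- grepl(rpat, cigar, perl = TRUE)
  right[has] <- as.integer(sub(paste0("^.*?", rpat), "\\1", cigar[has],
                               perl = TRUE))
  # a CIGAR that is pure clip (e.g. "100S") would count twice; impossible for
  # a mapped read, but guard anyway
  only_clip <- !grepl("[MIDN=X]", cigar)
  left[only_clip] <- 0L
  right[only_clip] <- 0L
  cbind(left = left, right = right)
}

phred_from_string <- function(qual) utf8ToInt(qual) - 33L

#' Extract filtered soft-clip candidates from a breakpoint search region
#'
#' Reads overlapping the region are kept when their CIGAR carries a soft
#' clip on the region's expected breakpoint side, they are not PCR/optical
#' duplicates, not secondary/supplementary, have mapping quality > 0, the
#' clip is at least `min_clip_len` bases, and the mean Phred quality of the
#' clipped bases is strictly greater than `qual_threshold` (a mean of
#' exactly `qual_threshold` is discarded). The anchor breakpoint is the
#' aligned base adjacent to the clip: the rightmost aligned base for right
#' clips, the leftmost for left clips.
#'
#' @param bam indexed BAM path.
#' @param region one breakpoint search region (row of
#'   [build_breakpoint_regions()] output, or any list with `chrom`, `start`,
#'   `end`, `breakpoint_side`, and optionally `pair_ids`, `fusion_id`,
#'   `partner_role`).
#' @param min_clip_len minimum clip length in bp (default 6).
#' @param qual_threshold mean clip base-quality cutoff (default 15; "15 or
#'   less" is discarded).
#' @return `data.frame` of candidates: `read_name`, `anchor_partner`,
#'   `clip_side`, `clip_seq`, `clip_quals`, `mean_clip_qual`,
#'   `anchor_breakpoint`, `chrom`, `pair_ids`; filter-stage counts in
#'   `attr(, "stage_counts")`.
#' @export
extract_clip_candidates <- function(bam, region, min_clip_len = 6L,
                                    qual_threshold = 15) {
  side <- match.arg(region$breakpoint_side, c("left", "right"))
  reads <- scan_region_reads(bam, region$chrom, region$start, region$end)
  empty <- data.frame(read_name = character(0), anchor_partner = character(0),
                      clip_side = character(0), clip_seq = character(0),
                      clip_quals = character(0), mean_clip_qual = numeric(0),
                      anchor_breakpoint = integer(0), chrom = character(0),
                      pair_ids = character(0), stringsAsFactors = FALSE)
  counts <- c(reads = nrow(reads), dropped_flags = 0L, dropped_no_clip = 0L,
              dropped_short_clip = 0L, dropped_low_qual = 0L, kept = 0L)
  if (nrow(reads) == 0L) {
    attr(empty, "stage_counts") <- counts
    return(empty)
  }
  ok_flags <- !reads$is_dup & !reads$is_secondary & !reads$is_supplementary &
    !is.na(reads$mapq) & reads$mapq > 0L
  counts["dropped_flags"] <- sum(!ok_flags)
  reads <- reads[ok_flags, , drop = FALSE]
  clips <- cigar_clip_lengths(reads$cigar)
  clen <- if (side == "left") clips[, "left"] else clips[, "right"]
  has_clip <- clen > 0L
  counts["dropped_no_clip"] <- sum(!has_clip)
  long_enough <- clen >= min_clip_len
  counts["dropped_short_clip"] <- sum(has_clip & !long_enough)
  keep <- has_clip & long_enough
  reads <- reads[keep, , drop = FALSE]
  clen <- clen[keep]
  if (nrow(reads) == 0L) {
    attr(empty, "stage_counts") <- counts
    return(empty)
  }
  rl <- nchar(reads$seq)
  if (side == "left") {
    clip_seq <- substr(reads$seq, 1L, clen)
    clip_quals <- substr(reads$qual, 1L, clen)
    anchor <- reads$pos
  } else {
    clip_seq <- substr(reads$seq, rl - clen + 1L, rl)
    clip_quals <- substr(reads$qual, rl - clen + 1L, rl)
    anchor <- reads$aln_end
  }
  mean_q <- vapply(clip_quals, function(q) mean(phred_from_string(q)),
                   numeric(1), USE.NAMES = FALSE)
  hq <- mean_q > qual_threshold
  counts["dropped_low_qual"] <- sum(!hq)
  counts["kept"] <- sum(hq)
  out <- data.frame(
    read_name = reads$read_name[hq],
    anchor_partner = rep(if (is.null(region$partner_role)) NA_character_ else
      region$partner_role, sum(hq)),
    clip_side = rep(side, sum(hq)),
    clip_seq = clip_seq[hq],
    clip_quals = clip_quals[hq],
    mean_clip_qual = mean_q[hq],
    anchor_breakpoint = anchor[hq],
    chrom = reads$chrom[hq],
    pair_ids = rep(if (is.null(region$pair_ids)) NA_character_ else
      region$pair_ids, sum(hq)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "stage_counts") <- counts
  out
}

# Substitution matrix over A/C/G/T/N: +2 match, -3 mismatch, N never matches.
clip_substitution_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Locally realign a soft-clipped sequence into the partner region
#'
#' Smith-Waterman local alignment (match +2, mismatch -3, gap opening 5,
#' gap extension 2; a gap of length L costs `5 + 2L`) of the clip against
#' the partner breakpoint search-region sequence, tried in both forward and
#' reverse-complement orientation; the better-scoring orientation wins (ties
#' go to forward). The alignment is accepted when at least `min_coverage` of
#' the clip is aligned and at least `min_identity` of the aligned columns
#' match; otherwise `NULL` is returned. The partner breakpoint is the
#' genomic coordinate of the junction-proximal end of the clip's alignment:
#' the position of the first clip base (the base adjacent to the anchor's
#' aligned segment) for right-side clips, of the last clip base for
#' left-side clips, after orientation bookkeeping.
#'
#' @param clip_seq clipped bases (read orientation as aligned).
#' @param partner_sequence reference sequence of the partner's breakpoint
#'   search region (character or `DNAString`).
#' @param partner_offset 1-based genomic start coordinate of
#'   `partner_sequence`.
#' @param clip_side `"left"` or `"right"`: which end of the anchored read
#'   carried this clip.
#' @param min_identity,min_coverage acceptance thresholds (defaults 0.9).
#' @return `NULL`, or a list with `orientation` (`"forward"` /
#'   `"reverse_complement"`), `score`, `identity`, `coverage`,
#'   `partner_breakpoint`.
#' @export
align_clip <- function(clip_seq, partner_sequence, partner_offset,
                       clip_side = c("right", "left"),
                       min_identity = 0.9, min_coverage = 0.9) {
  clip_side <- match.arg(clip_side)
  partner_sequence <- as.character(partner_sequence)
  if (nchar(partner_sequence) == 0L) {
    stop("align_clip: empty partner sequence", call. = FALSE)
  }
  clip_seq <- toupper(as.character(clip_seq))
  L <- nchar(clip_seq)
  mat <- clip_substitution_matrix()
  target <- Biostrings::DNAString(partner_sequence)
  aln_one <- function(query) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query), subject = target,
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
  }
  fwd <- aln_one(clip_seq)
  rc <- aln_one(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(clip_seq))))
  use_rc <- Biostrings::score(rc) > Biostrings::score(fwd)
  aln <- if (use_rc) rc else fwd
  orientation <- if (use_rc) "reverse_complement" else "forward"
  ps <- IRanges::start(Biostrings::pattern(aln))
  pe <- IRanges::end(Biostrings::pattern(aln))
  ss <- IRanges::start(Biostrings::subject(aln))
  se <- IRanges::end(Biostrings::subject(aln))
  ncol_aln <- nchar(as.character(Biostrings::pattern(aln)))
  identity <- if (ncol_aln > 0L) Biostrings::nmatch(aln) / ncol_aln else 0
  coverage <- (pe - ps + 1L) / L
  if (coverage < min_coverage || identity < min_identity) return(NULL)
  # junction-proximal clip base: first base for right clips, last for left
  q <- if (clip_side == "right") 1L else L
  qo <- if (use_rc) L - q + 1L else q  # index in the oriented query
  pos_local <- if (qo <= ps) {
    ss - (ps - qo)
  } else if (qo >= pe) {
    se + (qo - pe)
  } else {
    ss + (qo - ps)
  }
  list(orientation = orientation,
       score = Biostrings::score(aln),
       identity = identity,
       coverage = coverage,
       partner_breakpoint = as.integer(partner_offset) + pos_local - 1L)
}

#' Call genomic breakpoints from passing clip candidates
#'
#' Candidates (already accepted by [align_clip()]) are grouped per partner
#' and chromosome by their anchor breakpoint coordinate — exactly by
#' default, or single-linkage clustered when `merge_window > 0`, in which
#' case the reported coordinate is the one supported by most distinct reads
#' (ties to the smallest coordinate). Support is the number of distinct read
#' names; linked pair ids are inherited from the source regions.
#'
#' @param candidates `data.frame` with columns `read_name`,
#'   `anchor_partner`, `chrom`, `anchor_breakpoint`, `identity`,
#'   `orientation`, `pair_ids`.
#' @param merge_window coordinate fuzz for grouping (default 0 = exact).
#' @return `data.frame` of calls: `partner_role`, `chrom`, `coordinate`,
#'   `n_support_reads`, `mean_identity`, `orientations`, `support_reads`,
#'   `pair_ids`, sorted by descending support then coordinate.
#' @export
call_breakpoints <- function(candidates, merge_window = 0L) {
  empty <- data.frame(partner_role = character(0), chrom = character(0),
                      coordinate = integer(0), n_support_reads = integer(0),
                      mean_identity = numeric(0), orientations = character(0),
                      support_reads = character(0), pair_ids = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  res <- list()
  for (key in unique(paste(candidates$anchor_partner, candidates$chrom,
                           sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- candidates[candidates$anchor_partner == part[1L] &
                        candidates$chrom == part[2L], , drop = FALSE]
    sub <- sub[order(sub$anchor_breakpoint), , drop = FALSE]
    coords <- sub$anchor_breakpoint
    grp <- cumsum(c(1L, diff(coords) > merge_window))
    for (g in unique(grp)) {
      gg <- sub[grp == g, , drop = FALSE]
      # representative coordinate: max distinct-read support, ties smallest
      sup <- vapply(split(gg$read_name, gg$anchor_breakpoint),
                    function(x) length(unique(x)), integer(1))
      coord <- as.integer(names(sup)[which.max(sup)])  # which.max: first of ties
      dd <- gg[!duplicated(gg$read_name), , drop = FALSE]
      pair_ids <- sort(unique(unlist(strsplit(
        gg$pair_ids[!is.na(gg$pair_ids)], ",", fixed = TRUE))))
      ori_tab <- sort(table(dd$orientation), decreasing = TRUE)
      res[[length(res) + 1L]] <- data.frame(
        partner_role = part[1L], chrom = part[2L], coordinate = coord,
        n_support_reads = nrow(dd),
        mean_identity = mean(dd$identity),
        orientations = paste0(names(ori_tab), ":", as.integer(ori_tab),
                              collapse = ";"),
        support_reads = paste(sort(unique(gg$read_name)), collapse = ","),
        pair_ids = paste(pair_ids, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$n_support_reads, out$coordinate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the breakpoint-call table
#'
#' @param calls breakpoint-call `data.frame` (with `fusion_id`, `sample_id`
#'   columns added by the pipeline).
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_breakpoint_table <- function(calls, out_path) {
  cols <- c("fusion_id", "sample_id", "partner_role", "chrom", "coordinate",
            "n_support_reads", "mean_identity", "orientations",
            "support_reads", "pair_ids")
  if (is.null(calls) || nrow(calls) == 0L) {
    calls <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols))
  }
  write_tsv(calls[, cols, drop = FALSE], out_path)
}
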