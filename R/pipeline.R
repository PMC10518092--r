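#' @title Pipeline orchestration
#' @description Run the full validation over every fusion in an input table:
#'   discordant-pair extraction, breakpoint-region construction, soft-clip
#'   realignment and breakpoint calling, with per-stage logging.
#' @name pipeline
NULL

#' Run configuration
#'
#' Collects every user-tunable threshold with the pipeline defaults: the
#' 4 kb intrachromosomal fragment cutoff, the 500 bp junction / 2 kb gene
#' search-region pads, the 500/50 bp breakpoint-region pads, the 6 bp
#' minimum clip length, the mean clip quality cutoff of 15, the clip
#' realignment acceptance thresholds (identity and coverage 0.9), and the
#' breakpoint merge window (0 = exact coordinates).
#'
#' @param min_fragment intrachromosomal fragment-span cutoff (bp).
#' @param pad_junction,pad_gene search-region pads (bp).
#' @param bp_pad_toward,bp_pad_opposite breakpoint-region pads (bp).
#' @param min_clip_len minimum soft-clip length (bp).
#' @param clip_qual_threshold mean clip Phred cutoff (strictly-greater pass).
#' @param clip_identity,clip_coverage clip-realignment acceptance fractions.
#' @param breakpoint_merge_window coordinate fuzz when grouping breakpoints.
#' @param high_support_pairs discordant-pair count for the high-support flag.
#' @return a `run_config` list.
#' @export
run_config <- function(min_fragment = 4000L,
                       pad_junction = 500L, pad_gene = 2000L,
                       bp_pad_toward = 500L, bp_pad_opposite = 50L,
                       min_clip_len = 6L, clip_qual_threshold = 15,
                       clip_identity = 0.9, clip_coverage = 0.9,
                       breakpoint_merge_window = 0L,
                       high_support_pairs = 5L) {
  cfg <- list(min_fragment = as.integer(min_fragment),
              pad_junction = as.integer(pad_junction),
              pad_gene = as.integer(pad_gene),
              bp_pad_toward = as.integer(bp_pad_toward),
              bp_pad_opposite = as.integer(bp_pad_opposite),
              min_clip_len = as.integer(min_clip_len),
              clip_qual_threshold = clip_qual_threshold,
              clip_identity = clip_identity,
              clip_coverage = clip_coverage,
              breakpoint_merge_window = as.integer(breakpoint_merge_window),
              high_support_pairs = as.integer(high_support_pairs))
  stopifnot(all(vapply(cfg, function(x) is.finite(x) && x >= 0, logical(1))))
  structure(cfg, class = "run_config")
}

#' Validate one fusion record against its BAM
#'
#' Collects discordant pairs for the record's search regions; when at least
#' one pair survives filtering, builds breakpoint search regions around the
#' discordant reads in each partner, extracts and filters soft-clip
#' candidates, realigns each clip into the opposite partner's breakpoint
#' region sequence, and calls breakpoints.
#'
#' @param record one fusion-table row.
#' @param reference path to the indexed reference FASTA.
#' @param config a [run_config()].
#' @param bam optional BAM path overriding the record's `path` column.
#' @return list with `pairs`, `breakpoints` (data.frames), and `log`
#'   (per-stage counts).
#' @export
validate_fusion <- function(record, reference, config = run_config(),
                            bam = NULL) {
  bam <- if (is.null(bam)) record$path else bam
  check_bam(bam)
  chrom_lengths <- bam_chrom_lengths(bam)
  regions <- regions_from_record(record, chrom_lengths)
  pairs <- collect_discordant_pairs(bam, record, regions$five, regions$three,
                                    min_fragment = config$min_fragment)
  log <- list(discordant = attr(pairs, "stage_counts"))
  bp_calls <- NULL
  if (nrow(pairs) > 0L) {
    fa <- Rsamtools::FaFile(reference)
    roles <- list(five_prime = list(region = regions$five, prefix = "r5"),
                  three_prime = list(region = regions$three, prefix = "r3"))
    # breakpoint search regions per partner, from that partner's mates
    bp_regions <- lapply(roles, function(role) {
      p <- role$prefix
      build_breakpoint_regions(
        data.frame(start = pairs[[paste0(p, "_pos")]],
                   end = pairs[[paste0(p, "_aln_end")]],
                   pair_id = pairs$pair_id, stringsAsFactors = FALSE),
        side = role$region$breakpoint_side,
        fusion_id = record$fusion_id,
        partner_role = role$region$partner_role,
        chrom = role$region$chrom,
        pad_toward = config$bp_pad_toward,
        pad_opposite = config$bp_pad_opposite,
        chrom_length = chrom_lengths[[role$region$chrom]])
    })
    # reference slice of each partner's breakpoint regions (alignment target
    # for clips anchored in the opposite partner)
    slices <- lapply(bp_regions, function(br) {
      if (nrow(br) == 0L) return(NULL)
      lo <- min(br$start); hi <- max(br$end)
      gr <- GenomicRanges::GRanges(br$chrom[1L], IRanges::IRanges(lo, hi))
      list(seq = as.character(Rsamtools::scanFa(fa, gr)[[1L]]), offset = lo)
    })
    cands <- list()
    clip_log <- list()
    for (role_name in names(roles)) {
      br <- bp_regions[[role_name]]
      for (k in seq_len(nrow(br))) {
        cc <- extract_clip_candidates(bam, br[k, ],
                                      min_clip_len = config$min_clip_len,
                                      qual_threshold = config$clip_qual_threshold)
        clip_log[[length(clip_log) + 1L]] <- attr(cc, "stage_counts")
        if (nrow(cc) > 0L) cands[[length(cands) + 1L]] <- cc
      }
    }
    log$clip_stages <- if (length(clip_log)) Reduce(`+`, clip_log) else NULL
    passing <- list()
    if (length(cands) > 0L) {
      cands <- do.call(rbind, cands)
      # same read may surface from overlapping regions of the two partners;
      # candidates are per (read, anchor partner)
      cands <- cands[!duplicated(paste(cands$read_name, cands$anchor_partner)),
                     , drop = FALSE]
      for (k in seq_len(nrow(cands))) {
        other <- if (cands$anchor_partner[k] == "five_prime")
          "three_prime" else "five_prime"
        sl <- slices[[other]]
        if (is.null(sl)) next
        hit <- align_clip(cands$clip_seq[k], sl$seq, sl$offset,
                          clip_side = cands$clip_side[k],
                          min_identity = config$clip_identity,
                          min_coverage = config$clip_coverage)
        if (is.null(hit)) next
        row <- cands[k, , drop = FALSE]
        row$orientation <- hit$orientation
        row$score <- hit$score
        row$identity <- hit$identity
        row$coverage <- hit$coverage
        row$partner_breakpoint <- hit$partner_breakpoint
        passing[[length(passing) + 1L]] <- row
      }
    }
    if (length(passing) > 0L) {
      passing <- do.call(rbind, passing)
      bp_calls <- call_breakpoints(passing,
                                   merge_window = config$breakpoint_merge_window)
      if (nrow(bp_calls) > 0L) {
        bp_calls <- cbind(fusion_id = record$fusion_id,
                          sample_id = record$sample_id, bp_calls,
                          stringsAsFactors = FALSE)
      }
      log$clip_passing <- nrow(passing)
    } else {
      log$clip_passing <- 0L
    }
  }
  list(pairs = pairs, breakpoints = bp_calls, log = log)
}

#' Run the validation pipeline over a fusion table
#'
#' Iterates over every fusion in the input table, collects discordant pairs
#' and — when any are found — genomic breakpoints, and writes three
#' tab-separated outputs into `output_dir`: `discordant_pairs.tsv`,
#' `breakpoints.tsv` and `summary.tsv` (one summary row per input fusion,
#' with `validated`, `breakpoint_found` and `high_support` flags). Absence
#' of support is a result, not an error. A per-fusion filter-stage log is
#' written to `run_log.tsv`.
#'
#' @param input_table path to the fusion table TSV (or an already-loaded
#'   fusion-table `data.frame`).
#' @param reference path to the indexed reference FASTA.
#' @param output_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param bam optional single-BAM override applied to all rows.
#' @param quiet suppress progress messages.
#' @return the summary `data.frame`, invisibly; `pairs` and `breakpoints`
#'   tables attached as attributes.
#' @export
run_pipeline <- function(input_table, reference, output_dir,
                         config = run_config(), bam = NULL, quiet = TRUE) {
  fusions <- if (is.data.frame(input_table)) input_table else
    load_fusion_table(input_table)
  if (!file.exists(reference)) {
    stop("reference FASTA not found: ", reference, call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  all_pairs <- list()
  all_bps <- list()
  log_rows <- list()
  for (i in seq_len(nrow(fusions))) {
    record <- fusions[i, , drop = FALSE]
    res <- tryCatch(
      validate_fusion(record, reference, config = config, bam = bam),
      error = function(e) {
        stop("fusion '", record$fusion_id, "' (row ", i, "): ",
             conditionMessage(e), call. = FALSE)
      })
    if (nrow(res$pairs) > 0L) all_pairs[[length(all_pairs) + 1L]] <- res$pairs
    if (!is.null(res$breakpoints) && nrow(res$breakpoints) > 0L) {
      all_bps[[length(all_bps) + 1L]] <- res$breakpoints
    }
    dc <- res$log$discordant
    log_rows[[i]] <- data.frame(
      fusion_id = record$fusion_id, t(as.matrix(dc)),
      clip_passing = if (is.null(res$log$clip_passing)) 0L else
        res$log$clip_passing,
      stringsAsFactors = FALSE)
    if (!quiet) {
      message(sprintf("fusion %s: %d discordant pair(s), %d breakpoint(s)",
                      record$fusion_id, dc[["kept"]],
                      if (is.null(res$breakpoints)) 0L else
                        nrow(res$breakpoints)))
    }
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else NULL
  bps <- if (length(all_bps)) do.call(rbind, all_bps) else NULL
  summary <- summarize_fusions(fusions, pairs, bps,
                               high_support_pairs = config$high_support_pairs)
  write_pair_table(pairs, file.path(output_dir, "discordant_pairs.tsv"))
  write_breakpoint_table(bps, file.path(output_dir, "breakpoints.tsv"))
  write_summary_table(summary, file.path(output_dir, "summary.tsv"))
  if (length(log_rows)) {
    write_tsv(do.call(rbind, log_rows), file.path(output_dir, "run_log.tsv"))
  }
  attr(summary, "pairs") <- pairs
  attr(summary, "breakpoints") <- bps
  invisible(summary)
}
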