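#' @title Fusion input-table I/O
#' @description Read and validate the 13-column fusion input schema, and write
#'   the pipeline's discordant-pair and per-fusion summary tables.
#' @name fusion_table
NULL

FUSION_TABLE_COLUMNS <- c(
  "fusion_id", "sample_id", "path",
  "fiveprime_chr", "fiveprime_strand", "fiveprime_junction",
  "fiveprime_search_start", "fiveprime_search_end",
  "threeprime_chr", "threeprime_strand", "threeprime_junction",
  "threeprime_search_start", "threeprime_search_end"
)

FUSION_COORD_COLUMNS <- c(
  "fiveprime_junction", "fiveprime_search_start", "fiveprime_search_end",
  "threeprime_junction", "threeprime_search_start", "threeprime_search_end"
)

#' Normalize a strand token
#'
#' Accepts `"+"`, `"-"` and the typographic minus sign `"−"`, returning
#' `"+"` or `"-"`. Any other token is an error.
#'
#' @param x character vector of strand tokens.
#' @return character vector of `"+"`/`"-"`.
#' @export
normalize_strand <- function(x) {
  x <- trimws(as.character(x))
  x[x == "−"] <- "-"
  bad <- !(x %in% c("+", "-"))
  if (any(bad)) {
    stop("invalid strand token(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected '+' or '-')", call. = FALSE)
  }
  x
}

# Parse 1-based coordinates, tolerating thousands separators ("55,013,468").
parse_coordinate <- function(x, column, rows) {
  raw <- gsub(",", "", trimws(as.character(x)), fixed = TRUE)
  suppressWarnings(val <- as.numeric(raw))
  bad <- is.na(val) | val != floor(val)
  bad[is.na(x) | raw == ""] <- TRUE
  if (any(bad)) {
    stop(sprintf("column '%s': non-numeric coordinate in row %s (value '%s')",
                 column, rows[which(bad)[1L]], x[which(bad)[1L]]),
         call. = FALSE)
  }
  as.integer(val)
}

#' Load a fusion input table
#'
#' Reads a tab-separated fusion table with the 13 required columns
#' (`fusion_id`, `sample_id`, `path`, and per-partner
#' `chr`/`strand`/`junction`/`search_start`/`search_end`). Column order is
#' irrelevant; extra columns are dropped. Coordinates are 1-based inclusive
#' and may contain thousands separators; strands may use the typographic
#' minus. Each record is validated: `search_start <= search_end` and the
#' junction must lie inside its search interval, for both partners.
#'
#' @param tsv_path path to the tab-separated table (with header row).
#' @return a `data.frame` with one row per fusion, coordinates as integers,
#'   strands normalized to `"+"`/`"-"`, in input order.
#' @export
load_fusion_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    stop("fusion table not found: ", tsv_path, call. = FALSE)
  }
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(FUSION_TABLE_COLUMNS, names(tab))
  if (length(missing_cols) > 0L) {
    stop("fusion table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, FUSION_TABLE_COLUMNS, drop = FALSE]
  if (nrow(tab) == 0L) {
    for (cc in FUSION_COORD_COLUMNS) tab[[cc]] <- integer(0)
    return(tab)
  }
  rows <- seq_len(nrow(tab)) + 1L  # 1-based file row (header is row 1)
  for (cc in FUSION_COORD_COLUMNS) {
    tab[[cc]] <- parse_coordinate(tab[[cc]], cc, rows)
  }
  tab$fiveprime_strand <- normalize_strand(tab$fiveprime_strand)
  tab$threeprime_strand <- normalize_strand(tab$threeprime_strand)

  dup <- duplicated(tab$fusion_id)
  if (any(dup)) {
    stop("duplicate fusion_id value(s): ",
         paste(unique(tab$fusion_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (side in c("fiveprime", "threeprime")) {
    ss <- tab[[paste0(side, "_search_start")]]
    se <- tab[[paste0(side, "_search_end")]]
    jn <- tab[[paste0(side, "_junction")]]
    bad <- ss > se
    if (any(bad)) {
      stop(sprintf("fusion '%s': %s_search_start > %s_search_end",
                   tab$fusion_id[which(bad)[1L]], side, side), call. = FALSE)
    }
    out <- jn < ss | jn > se
    if (any(out)) {
      stop(sprintf("fusion '%s': %s_junction outside [%s_search_start, %s_search_end]",
                   tab$fusion_id[which(out)[1L]], side, side, side),
           call. = FALSE)
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Write a fusion table
#'
#' Inverse of [load_fusion_table()]: writes the 13-column schema as clean TSV
#' (no thousands separators, ASCII strands).
#'
#' @param tab fusion table `data.frame`.
#' @param out_path output path.
#' @return `out_path`, invisibly.
#' @export
write_fusion_table <- function(tab, out_path) {
  write_tsv(tab[, FUSION_TABLE_COLUMNS, drop = FALSE], out_path)
}

# Shared TSV writer: UTF-8, tab-delimited, header, no quoting.
write_tsv <- function(df, out_path) {
  ok <- tryCatch({
    utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write table to '", out_path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(out_path)
}

PAIR_TABLE_COLUMNS <- c(
  "fusion_id", "sample_id", "pair_id", "read_name",
  "r5_chrom", "r5_pos", "r5_aln_end", "r5_mapq", "r5_flag", "r5_cigar",
  "r5_mate_chrom", "r5_mate_pos", "r5_tlen",
  "r3_chrom", "r3_pos", "r3_aln_end", "r3_mapq", "r3_flag", "r3_cigar",
  "r3_mate_chrom", "r3_mate_pos", "r3_tlen",
  "fragment_span"
)

#' Write the discordant-pair table
#'
#' One row per discordant pair with per-mate alignment detail (chromosome,
#' 1-based position, MAPQ, flag, CIGAR, mate chromosome/position, template
#' length) for the mate in the 5' region (`r5_*`) and in the 3' region
#' (`r3_*`). Rows are ordered by `fusion_id`, then read name, so repeated
#' runs are byte-identical.
#'
#' @param pairs discordant-pair `data.frame` as returned by
#'   [collect_discordant_pairs()] (possibly row-bound across fusions).
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_pair_table <- function(pairs, out_path) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(PAIR_TABLE_COLUMNS)),
                                    PAIR_TABLE_COLUMNS))
    return(write_tsv(empty, out_path))
  }
  pairs <- pairs[order(pairs$fusion_id, pairs$read_name), , drop = FALSE]
  write_tsv(pairs[, PAIR_TABLE_COLUMNS, drop = FALSE], out_path)
}

#' Summarize per-fusion validation status
#'
#' A fusion is `validated` when at least one discordant read pair supports
#' it; `breakpoint_found` when a genomic breakpoint was called in either
#' partner; `high_support` when it has at least `high_support_pairs`
#' discordant pairs and/or an identified breakpoint.
#'
#' @param fusions fusion table (provides `fusion_id`/`sample_id`; every row
#'   yields a summary row, including unsupported fusions).
#' @param pairs discordant-pair table (may be empty/NULL).
#' @param breakpoints breakpoint-call table (may be empty/NULL).
#' @param high_support_pairs pair count at which support is called high
#'   (default 5).
#' @return `data.frame` with columns `fusion_id`, `sample_id`,
#'   `n_discordant_pairs`, `validated`, `breakpoint_found`, `high_support`.
#' @export
summarize_fusions <- function(fusions, pairs = NULL, breakpoints = NULL,
                              high_support_pairs = 5L) {
  n_pairs <- integer(nrow(fusions))
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    cnt <- table(pairs$fusion_id)
    idx <- match(fusions$fusion_id, names(cnt))
    n_pairs <- ifelse(is.na(idx), 0L, as.integer(cnt)[idx])
  }
  bp_found <- logical(nrow(fusions))
  if (!is.null(breakpoints) && nrow(breakpoints) > 0L) {
    bp_found <- fusions$fusion_id %in% breakpoints$fusion_id
  }
  validated <- n_pairs >= 1L
  # breakpoints are only searched near discordant reads
  bp_found <- bp_found & validated
  data.frame(
    fusion_id = fusions$fusion_id,
    sample_id = fusions$sample_id,
    n_discordant_pairs = n_pairs,
    validated = validated,
    breakpoint_found = bp_found,
    high_support = n_pairs >= high_support_pairs | bp_found,
    stringsAsFactors = FALSE
  )
}

#' Write the per-fusion summary table
#'
#' @param summaries `data.frame` from [summarize_fusions()].
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_summary_table <- function(summaries, out_path) {
  cols <- c("fusion_id", "sample_id", "n_discordant_pairs",
            "validated", "breakpoint_found", "high_support")
  write_tsv(summaries[, cols, drop = FALSE], out_path)
}
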