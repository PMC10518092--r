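#' @title Search-region geometry
#' @description Junction-anchored partner search regions and breakpoint
#'   search regions around discordant reads.
#' @name regions
NULL

#' Gene bounds
#'
#' A gene span in genomic coordinates: `genomic_start <= genomic_end`
#' regardless of strand, 1-based inclusive.
#'
#' @param chrom chromosome name.
#' @param genomic_start,genomic_end 1-based inclusive span.
#' @param strand `"+"` or `"-"` (typographic minus accepted).
#' @return a `gene_bounds` list.
#' @export
gene_bounds <- function(chrom, genomic_start, genomic_end, strand) {
  genomic_start <- as.integer(genomic_start)
  genomic_end <- as.integer(genomic_end)
  if (genomic_start > genomic_end) {
    stop("gene_bounds: genomic_start > genomic_end", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), genomic_start = genomic_start,
                 genomic_end = genomic_end, strand = normalize_strand(strand)),
            class = "gene_bounds")
}

#' Side of a partner's search region where the DNA breakpoint is expected
#'
#' The genomic direction (left = lower coordinates, right = higher) in which
#' the genomic breakpoint lies relative to the fusion junction, determined by
#' partner role and strand. Fusion-supporting DNA lies downstream (in
#' transcriptional direction) of the junction for the 5' partner and upstream
#' for the 3' partner; translating transcript direction into genome direction
#' gives: (5', +) right; (5', -) left; (3', +) left; (3', -) right.
#'
#' @param partner_role `"five_prime"` or `"three_prime"`.
#' @param strand `"+"` or `"-"`.
#' @return `"left"` or `"right"`.
#' @export
breakpoint_side <- function(partner_role, strand) {
  partner_role <- match.arg(partner_role, c("five_prime", "three_prime"))
  strand <- normalize_strand(strand)
  if (partner_role == "five_prime") {
    if (strand == "+") "right" else "left"
  } else {
    if (strand == "+") "left" else "right"
  }
}

#' Construct a search region
#'
#' @param fusion_id fusion identifier.
#' @param partner_role `"five_prime"` or `"three_prime"`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @param side `"left"` or `"right"` breakpoint side.
#' @return a `search_region` list.
#' @export
search_region <- function(fusion_id, partner_role, chrom, start, end, side) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (start > end) stop("search_region: start > end", call. = FALSE)
  if (start < 1L) stop("search_region: start < 1", call. = FALSE)
  structure(list(fusion_id = as.character(fusion_id),
                 partner_role = match.arg(partner_role,
                                          c("five_prime", "three_prime")),
                 chrom = as.character(chrom),
                 start = start, end = end,
                 breakpoint_side = match.arg(side, c("left", "right"))),
            class = "search_region")
}

#' Compute a junction-anchored search region from gene bounds
#'
#' The region spans, in genomic coordinates, the interval between the fusion
#' junction and the transcriptional end of the gene (5' partner) or the
#' transcriptional start (3' partner), padded by `pad_junction` beyond the
#' junction and `pad_gene` beyond the gene boundary. For a plus-strand 5'
#' partner the transcriptional gene end is the genomic right bound, so the
#' region runs rightward from the junction; minus-strand partners have their
#' genomic start and end switched accordingly. The result is clamped at
#' coordinate 1 (and at `chrom_length` when known).
#'
#' @param junction 1-based junction coordinate.
#' @param gene a [gene_bounds()] object on the same chromosome.
#' @param partner_role `"five_prime"` or `"three_prime"`.
#' @param fusion_id fusion identifier carried on the result.
#' @param pad_junction padding (bp) beyond the junction (default 500).
#' @param pad_gene padding (bp) beyond the gene boundary (default 2000).
#' @param chrom_length optional contig length for right-edge clamping.
#' @return a [search_region()].
#' @export
compute_search_region <- function(junction, gene, partner_role,
                                  fusion_id = NA_character_,
                                  pad_junction = 500L, pad_gene = 2000L,
                                  chrom_length = NULL) {
  stopifnot(inherits(gene, "gene_bounds"), pad_junction >= 0, pad_gene >= 0)
  junction <- as.integer(junction)
  if (junction < gene$genomic_start - pad_junction ||
      junction > gene$genomic_end + pad_junction) {
    stop(sprintf("junction %d outside padded gene span [%d, %d]",
                 junction, gene$genomic_start - as.integer(pad_junction),
                 gene$genomic_end + as.integer(pad_junction)), call. = FALSE)
  }
  side <- breakpoint_side(partner_role, gene$strand)
  if (side == "right") {
    start <- junction - as.integer(pad_junction)
    end <- gene$genomic_end + as.integer(pad_gene)
  } else {
    start <- gene$genomic_start - as.integer(pad_gene)
    end <- junction + as.integer(pad_junction)
  }
  start <- max(1L, start)
  if (!is.null(chrom_length)) end <- min(as.integer(chrom_length), end)
  end <- max(end, start)
  search_region(fusion_id, partner_role, gene$chrom, start, end, side)
}

#' Search regions for both partners of a fusion-table record
#'
#' Uses the precomputed search bounds carried in the input table verbatim
#' (the table schema ships them); breakpoint sides come from the role/strand
#' decision table.
#'
#' @param record one row of a fusion table (`data.frame` row or list).
#' @param chrom_lengths optional named vector of contig lengths for clamping.
#' @return list with elements `five` and `three`, each a [search_region()].
#' @export
regions_from_record <- function(record, chrom_lengths = NULL) {
  clamp <- function(chrom, start, end) {
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      end <- min(end, as.integer(chrom_lengths[[chrom]]))
    }
    c(max(1L, as.integer(start)), as.integer(end))
  }
  b5 <- clamp(record$fiveprime_chr, record$fiveprime_search_start,
              record$fiveprime_search_end)
  b3 <- clamp(record$threeprime_chr, record$threeprime_search_start,
              record$threeprime_search_end)
  list(
    five = search_region(record$fusion_id, "five_prime", record$fiveprime_chr,
                         b5[1L], b5[2L],
                         breakpoint_side("five_prime", record$fiveprime_strand)),
    three = search_region(record$fusion_id, "three_prime", record$threeprime_chr,
                          b3[1L], b3[2L],
                          breakpoint_side("three_prime", record$threeprime_strand))
  )
}

#' Build breakpoint search regions around discordant reads
#'
#' A genomic breakpoint can only lie within about one fragment length of a
#' discordant read, so each read interval is extended by `pad_toward` in the
#' direction of the expected breakpoint and `pad_opposite` the other way.
#' Extended intervals that overlap or touch are merged (coordinate union) so
#' the same reads are not fetched twice; merged regions keep the union of the
#' contributing pair ids.
#'
#' @param reads `data.frame` with columns `start`, `end` (1-based inclusive
#'   read alignment span) and `pair_id`; all on one chromosome, one fusion,
#'   one partner role.
#' @param side `"left"` or `"right"`: direction of the expected breakpoint.
#' @param fusion_id,partner_role,chrom metadata carried on the result.
#' @param pad_toward padding toward the breakpoint (default 500).
#' @param pad_opposite padding away from it (default 50).
#' @param chrom_length optional contig length for clamping.
#' @return `data.frame` with columns `fusion_id`, `partner_role`, `chrom`,
#'   `start`, `end`, `breakpoint_side`, `pair_ids` (comma-joined), sorted by
#'   `start`; zero rows for empty input.
#' @export
build_breakpoint_regions <- function(reads, side,
                                     fusion_id = NA_character_,
                                     partner_role = NA_character_,
                                     chrom = NA_character_,
                                     pad_toward = 500L, pad_opposite = 50L,
                                     chrom_length = NULL) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(pad_toward >= 0, pad_opposite >= 0)
  empty <- data.frame(fusion_id = character(0), partner_role = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), breakpoint_side = character(0),
                      pair_ids = character(0), stringsAsFactors = FALSE)
  if (is.null(reads) || nrow(reads) == 0L) return(empty)
  if (side == "right") {
    ext_start <- as.integer(reads$start) - as.integer(pad_opposite)
    ext_end <- as.integer(reads$end) + as.integer(pad_toward)
  } else {
    ext_start <- as.integer(reads$start) - as.integer(pad_toward)
    ext_end <- as.integer(reads$end) + as.integer(pad_opposite)
  }
  ext_start <- pmax(1L, ext_start)
  if (!is.null(chrom_length)) ext_end <- pmin(as.integer(chrom_length), ext_end)
  ir <- IRanges::IRanges(start = ext_start, end = ext_end)
  merged <- IRanges::reduce(ir)  # default min.gapwidth = 1 merges abutting
  hits <- IRanges::findOverlaps(ir, merged)
  grp <- S4Vectors::subjectHits(hits)
  ids <- split(reads$pair_id[S4Vectors::queryHits(hits)], grp)
  pair_ids <- vapply(seq_along(merged), function(i) {
    paste(sort(unique(ids[[as.character(i)]])), collapse = ",")
  }, character(1))
  out <- data.frame(
    fusion_id = fusion_id, partner_role = partner_role, chrom = chrom,
    start = IRanges::start(merged), end = IRanges::end(merged),
    breakpoint_side = side, pair_ids = pair_ids, stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Read gene bounds from BED or TSV
#'
#' BED input (detected by the `.bed` extension) is 0-based half-open and is
#' converted to 1-based inclusive; otherwise a headerless 4-column TSV
#' (chrom, start, end, strand; 1-based inclusive) is expected.
#'
#' @param path input file.
#' @return `data.frame` with columns `chrom`, `genomic_start`,
#'   `genomic_end`, `strand` (1-based inclusive).
#' @export
read_gene_bounds <- function(path) {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) {
    stop("gene-bounds file needs at least 4 columns (chrom, start, end, strand)",
         call. = FALSE)
  }
  strand_col <- if (is_bed && ncol(tab) >= 6L) 6L else 4L
  out <- data.frame(
    chrom = as.character(tab[[1L]]),
    genomic_start = as.integer(tab[[2L]]) + if (is_bed) 1L else 0L,
    genomic_end = as.integer(tab[[3L]]),
    strand = normalize_strand(tab[[strand_col]]),
    stringsAsFactors = FALSE
  )
  out
}
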