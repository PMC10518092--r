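# Soft-clip extraction filters, clip realignment against a brute-force
# dynamic-programming oracle, and breakpoint grouping.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

phred_string <- function(q) intToUtf8(as.integer(q) + 33L)

clip_region <- function(chrom = "chrA", start, end, side,
                        partner = "five_prime") {
  list(chrom = chrom, start = start, end = end, breakpoint_side = side,
       partner_role = partner, pair_ids = "f:p1")
}

test_that("CIGAR arithmetic places the anchor breakpoint next to the clip", {
  chroms <- c(chrA = 100000L)
  recs <- list(
    list(qname = "rclip", flag = 0L, chrom = "chrA", pos = 5000L,
         cigar = "70M30S", qual = strrep(phred_string(30), 100L)),
    list(qname = "lclip", flag = 0L, chrom = "chrA", pos = 6000L,
         cigar = "30S70M", qual = strrep(phred_string(30), 100L))
  )
  bam <- write_mini_bam(recs, chroms)
  right <- extract_clip_candidates(bam, clip_region(start = 4500L, end = 5500L,
                                                    side = "right"))
  expect_identical(right$read_name, "rclip")
  expect_identical(right$anchor_breakpoint, 5000L + 70L - 1L)
  expect_identical(nchar(right$clip_seq), 30L)
  expect_identical(right$clip_side, "right")
  left <- extract_clip_candidates(bam, clip_region(start = 5500L, end = 6500L,
                                                   side = "left"))
  expect_identical(left$read_name, "lclip")
  expect_identical(left$anchor_breakpoint, 6000L)
  # a right-side region never yields the left-clipped read
  wrong <- extract_clip_candidates(bam, clip_region(start = 5500L, end = 6500L,
                                                    side = "right"))
  expect_equal(nrow(wrong), 0L)
})

test_that("clip length and quality filters sit exactly on the stated bounds", {
  chroms <- c(chrA = 100000L)
  qual96 <- strrep(phred_string(30), 95L)
  recs <- list(
    list(qname = "len5", flag = 0L, chrom = "chrA", pos = 5000L,
         cigar = "95M5S", qual = paste0(qual96, strrep(phred_string(30), 5L))),
    list(qname = "len6", flag = 0L, chrom = "chrA", pos = 5000L,
         cigar = "94M6S", qual = paste0(strrep(phred_string(30), 94L),
                                        strrep(phred_string(30), 6L))),
    # mean clip quality exactly 15.0 -> discarded
    list(qname = "q150", flag = 0L, chrom = "chrA", pos = 5000L,
         cigar = "90M10S", qual = paste0(strrep(phred_string(30), 90L),
                                         strrep(phred_string(15), 10L))),
    # mean clip quality 15.1 -> kept (nine 15s and one 16)
    list(qname = "q151", flag = 0L, chrom = "chrA", pos = 5000L,
         cigar = "90M10S", qual = paste0(strrep(phred_string(30), 90L),
                                         strrep(phred_string(15), 9L),
                                         phred_string(16))),
    # duplicates and MAPQ 0 are dropped before clip inspection
    list(qname = "dupl", flag = 1024L, chrom = "chrA", pos = 5000L,
         cigar = "70M30S", qual = strrep(phred_string(30), 100L)),
    list(qname = "mq0", flag = 0L, chrom = "chrA", pos = 5000L, mapq = 0L,
         cigar = "70M30S", qual = strrep(phred_string(30), 100L))
  )
  bam <- write_mini_bam(recs, chroms)
  reg <- clip_region(start = 4500L, end = 5500L, side = "right")
  got <- extract_clip_candidates(bam, reg)
  expect_setequal(got$read_name, c("len6", "q151"))
  expect_equal(got$mean_clip_qual[got$read_name == "q151"], 15.1)
  # monotonicity: raising either threshold never adds candidates
  base_n <- nrow(got)
  for (mcl in c(7L, 11L, 31L)) {
    expect_lte(nrow(extract_clip_candidates(bam, reg, min_clip_len = mcl)),
               base_n)
  }
  for (qt in c(16, 29, 30)) {
    expect_lte(nrow(extract_clip_candidates(bam, reg, qual_threshold = qt)),
               base_n)
  }
})

test_that("exact clips align with full identity and the expected breakpoint", {
  set.seed(41)
  target <- random_seq(1000L)
  offset <- 20001L
  clip <- substr(target, 301L, 320L)
  hit <- align_clip(clip, target, offset, clip_side = "right")
  expect_identical(hit$orientation, "forward")
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage, 1)
  expect_identical(hit$score, 40)  # 20 matches at +2
  # right-side clip, forward: breakpoint at the first clip base
  expect_identical(hit$partner_breakpoint, offset + 301L - 1L)

  # the same clip reverse-complemented in the reference
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clip)))
  hit_rc <- align_clip(rc, target, offset, clip_side = "right")
  expect_identical(hit_rc$orientation, "reverse_complement")
  expect_equal(hit_rc$identity, 1)
  # first clip base is the last base of the reverse-complement alignment
  expect_identical(hit_rc$partner_breakpoint, offset + 320L - 1L)

  # left-side clip, forward: breakpoint at the last clip base
  hit_l <- align_clip(clip, target, offset, clip_side = "left")
  expect_identical(hit_l$partner_breakpoint, offset + 320L - 1L)

  # a clip with no credible match is rejected
  expect_null(align_clip(strrep("ACGT", 5L), strrep("T", 200L), 1L,
                         clip_side = "right"))
  expect_error(align_clip("ACGTAC", "", 1L), "empty")
})

test_that("alignment scores equal the exhaustive DP oracle on random instances", {
  set.seed(43)
  for (i in 1:40) {
    clip <- random_seq(sample(6:20, 1L))
    target <- random_seq(sample(50:200, 1L))
    fwd <- oracle_local_align_score(clip, target)
    rc <- oracle_local_align_score(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(clip))), target)
    hit <- align_clip(clip, target, 1L, clip_side = "right",
                      min_identity = 0, min_coverage = 0)
    expect_equal(hit$score, max(fwd, rc))
  }
})

test_that("breakpoints group by exact coordinate with distinct-read support", {
  cand <- function(read, coord, partner = "five_prime", ori = "forward",
                   ident = 1) {
    data.frame(read_name = read, anchor_partner = partner, chrom = "chrA",
               anchor_breakpoint = coord, identity = ident, orientation = ori,
               pair_ids = paste0("f:", read), stringsAsFactors = FALSE)
  }
  # six distinct reads at one coordinate -> a single six-read call
  six <- do.call(rbind, lapply(sprintf("r%d", 1:6), cand, coord = 12345L))
  calls <- call_breakpoints(six)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$coordinate, 12345L)
  expect_identical(calls$n_support_reads, 6L)

  # the same read surfacing twice counts once
  twice <- rbind(cand("r1", 12345L), cand("r1", 12345L))
  expect_identical(call_breakpoints(twice)$n_support_reads, 1L)

  # 12,345 x4 and 12,346 x1 -> two calls with supports 4 and 1
  mix <- rbind(do.call(rbind, lapply(sprintf("a%d", 1:4), cand,
                                     coord = 12345L)),
               cand("b1", 12346L))
  calls <- call_breakpoints(mix)
  expect_identical(calls$coordinate, c(12345L, 12346L))
  expect_identical(calls$n_support_reads, c(4L, 1L))
  # with a one-base merge window the two coordinates collapse
  merged <- call_breakpoints(mix, merge_window = 1L)
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$coordinate, 12345L)
  expect_identical(merged$n_support_reads, 5L)
  # linked pairs are carried through
  expect_identical(merged$pair_ids,
                   paste(sort(c(sprintf("f:a%d", 1:4), "f:b1")),
                         collapse = ","))
})
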