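# Input-schema parsing, validation, and output-table round trips.

fusion_header <- paste(fuseval:::FUSION_TABLE_COLUMNS, collapse = "\t")

example_row <- function(fusion_id = "1",
                        fiveprime_junction = "55,013,468",
                        fiveprime_search_start = "54,956,927",
                        fiveprime_search_end = "55,013,968",
                        fiveprime_strand = "−") {
  paste(fusion_id, "sample_01", "~/raw_data/sample1/sample1.bam",
        "8", fiveprime_strand, fiveprime_junction, fiveprime_search_start,
        fiveprime_search_end,
        "8", "+", "61,531,139", "61,427,495", "61,531,639", sep = "\t")
}

write_table_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path, useBytes = FALSE)
  path
}

test_that("the documented example row parses with separators and typographic minus", {
  tab <- load_fusion_table(write_table_file(c(fusion_header, example_row())))
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$fiveprime_junction, 55013468L)
  expect_identical(tab$fiveprime_search_start, 54956927L)
  expect_identical(tab$fiveprime_search_end, 55013968L)
  expect_identical(tab$fiveprime_strand, "-")
  expect_identical(tab$threeprime_strand, "+")
  expect_identical(tab$threeprime_junction, 61531139L)
  expect_identical(tab$fiveprime_chr, "8")
})

test_that("column order is irrelevant and missing columns are named", {
  cols <- fuseval:::FUSION_TABLE_COLUMNS
  perm <- rev(cols)
  row <- strsplit(example_row(), "\t", fixed = TRUE)[[1L]]
  names(row) <- cols
  tab <- load_fusion_table(write_table_file(c(
    paste(perm, collapse = "\t"), paste(row[perm], collapse = "\t"))))
  expect_identical(tab$fiveprime_junction, 55013468L)
  expect_identical(names(tab), cols)

  dropped <- setdiff(cols, "threeprime_junction")
  expect_error(
    load_fusion_table(write_table_file(c(
      paste(dropped, collapse = "\t"), paste(row[dropped], collapse = "\t")))),
    "threeprime_junction")
})

test_that("parse and validation errors are specific", {
  expect_error(
    load_fusion_table(write_table_file(c(
      fusion_header, example_row(fiveprime_junction = "not_a_number")))),
    "row 2")
  # junction outside its search interval
  expect_error(
    load_fusion_table(write_table_file(c(
      fusion_header, example_row(fusion_id = "fx",
                                 fiveprime_junction = "54,000,000")))),
    "fx")
  # start > end
  expect_error(
    load_fusion_table(write_table_file(c(
      fusion_header,
      example_row(fiveprime_search_start = "55,900,000",
                  fiveprime_search_end = "55,013,968",
                  fiveprime_junction = "55,013,468")))),
    "search_start")
  expect_error(
    load_fusion_table(write_table_file(c(
      fusion_header, example_row("dup"), example_row("dup")))),
    "duplicate")
  expect_error(load_fusion_table(tempfile()), "not found")
})

test_that("a header-only file yields an empty table, not an error", {
  tab <- load_fusion_table(write_table_file(fusion_header))
  expect_equal(nrow(tab), 0L)
  expect_identical(names(tab), fuseval:::FUSION_TABLE_COLUMNS)
})

test_that("write + load round-trips records field for field", {
  tab <- load_fusion_table(write_table_file(c(
    fusion_header, example_row("a"),
    example_row("b", fiveprime_junction = "55,000,000"))))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_table(tab, out)
  # output is clean: no thousands separators, no typographic minus
  raw <- readLines(out)
  expect_false(any(grepl("[0-9],[0-9]", raw)))
  expect_false(any(grepl("−", raw)))
  expect_identical(load_fusion_table(out), tab)
})

test_that("summary flags follow the support rules", {
  fus <- data.frame(fusion_id = c("f1", "f2", "f3", "f4"),
                    sample_id = "s", stringsAsFactors = FALSE)
  pairs <- data.frame(
    fusion_id = c(rep("f1", 5L), "f2", rep("f4", 2L)),
    read_name = sprintf("r%02d", 1:8), stringsAsFactors = FALSE)
  bps <- data.frame(fusion_id = "f2", coordinate = 123L,
                    stringsAsFactors = FALSE)
  s <- summarize_fusions(fus, pairs, bps)
  expect_identical(s$fusion_id, fus$fusion_id)
  # 5 pairs, no breakpoint: high support by count alone
  expect_true(s$high_support[s$fusion_id == "f1"])
  expect_false(s$breakpoint_found[s$fusion_id == "f1"])
  # 1 pair + breakpoint: validated and high support
  expect_true(s$validated[s$fusion_id == "f2"])
  expect_true(s$high_support[s$fusion_id == "f2"])
  # no pairs: everything false
  expect_false(s$validated[s$fusion_id == "f3"])
  expect_false(s$breakpoint_found[s$fusion_id == "f3"])
  expect_false(s$high_support[s$fusion_id == "f3"])
  # 2 pairs, no breakpoint: validated but not high support
  expect_true(s$validated[s$fusion_id == "f4"])
  expect_false(s$high_support[s$fusion_id == "f4"])
  # invariant: validated false implies breakpoint_found false
  expect_true(all(s$breakpoint_found <= s$validated))
})

test_that("pair table rows are grouped by fusion and sorted by read name", {
  set.seed(11)
  n <- 10L
  pairs <- data.frame(
    fusion_id = sample(c("fB", "fA"), n, replace = TRUE),
    sample_id = "s", read_name = sample(sprintf("rd%02d", 1:n)),
    stringsAsFactors = FALSE)
  pairs$pair_id <- paste0(pairs$fusion_id, ":", pairs$read_name)
  for (p in c("r5", "r3")) {
    pairs[[paste0(p, "_chrom")]] <- "chr1"
    pairs[[paste0(p, "_pos")]] <- seq_len(n)
    pairs[[paste0(p, "_aln_end")]] <- seq_len(n) + 99L
    pairs[[paste0(p, "_mapq")]] <- 60L
    pairs[[paste0(p, "_flag")]] <- 99L
    pairs[[paste0(p, "_cigar")]] <- "100M"
    pairs[[paste0(p, "_mate_chrom")]] <- "chr1"
    pairs[[paste0(p, "_mate_pos")]] <- seq_len(n)
    pairs[[paste0(p, "_tlen")]] <- 0L
  }
  pairs$fragment_span <- NA_integer_
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(pairs, out)
  got <- utils::read.table(out, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_equal(nrow(got), n)
  # independent sort oracle over the row set
  want <- pairs[order(pairs$fusion_id, pairs$read_name), ]
  expect_identical(got$read_name, want$read_name)
  expect_identical(got$fusion_id, want$fusion_id)
  # round trip of a representative field
  expect_identical(got$r5_pos, want$r5_pos)

  write_pair_table(NULL, out)
  empty <- utils::read.table(out, header = TRUE, sep = "\t")
  expect_equal(nrow(empty), 0L)
  expect_true("read_name" %in% names(empty))
})
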