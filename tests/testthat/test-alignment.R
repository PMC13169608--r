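test_that("CIGAR strings parse to ordered operation lists", {
  ops <- parse_cigar("100M9703N50M")
  expect_identical(ops$op, c("M", "N", "M"))
  expect_identical(ops$length, c(100L, 9703L, 50L))
  expect_identical(nrow(parse_cigar("*")), 0L)
  expect_identical(parse_cigar("5S10M")$op, c("S", "M"))
  expect_error(parse_cigar("10M5"), "offset 4")
  expect_error(parse_cigar("M10"), "offset 1")
  expect_error(parse_cigar("10M#5N"), "offset 4")
})

test_that("aligned blocks follow reference-consumption semantics", {
  b <- aligned_blocks(rec(100, "50M1000N50M"))
  expect_equal(unname(b), cbind(c(100L, 1150L), c(150L, 1200L)),
               ignore_attr = TRUE)
  # deletions merge into the enclosing block
  b <- aligned_blocks(rec(100, "10M5D10M"))
  expect_equal(unname(b[, 1]), 100L)
  expect_equal(unname(b[, 2]), 125L)
  # soft clips consume no reference
  b <- aligned_blocks(rec(100, "5S20M"))
  expect_equal(unname(b[, 1]), 100L)
  expect_equal(unname(b[, 2]), 120L)
  expect_error(aligned_blocks(rec(0, "*", flag = 4L)), "mapped")
})

test_that("skipped intervals mirror the N operations in order", {
  s <- skipped_intervals(rec(100, "50M1000N50M"))
  expect_equal(unname(s), cbind(150L, 1150L), ignore_attr = TRUE)
  expect_identical(nrow(skipped_intervals(rec(100, "100M"))), 0L)
  s <- skipped_intervals(rec(0, "10M5N10M5N10M"))
  expect_equal(unname(s), cbind(c(10L, 25L), c(15L, 30L)),
               ignore_attr = TRUE)
})

test_that("block arithmetic is consistent with the CIGAR, clips aside", {
  set.seed(7)
  nl <- tiny_locus()
  rr <- random_records(200, nl, seed = 7)
  for (i in seq_len(nrow(rr))) {
    b <- aligned_blocks(rr[i, ])
    s <- skipped_intervals(rr[i, ])
    ops <- parse_cigar(rr$cigar[i])
    consumed <- sum(ops$length[ops$op %in% c("M", "=", "X", "D")])
    expect_identical(sum(b[, 2] - b[, 1]), as.integer(consumed))
    # no aligned block overlaps a skipped interval of the same record
    if (nrow(s)) {
      for (j in seq_len(nrow(s)))
        expect_true(all(b[, 2] <= s[j, 1] | b[, 1] >= s[j, 2]))
    }
  }
})

test_that("record filters honour flags and mapping quality", {
  f <- filter_config()
  expect_true(passes_filters(rec(10, "10M", flag = 0L, mapq = 255L), f))
  expect_false(passes_filters(rec(10, "10M", flag = 0x100L), f))
  expect_false(passes_filters(rec(10, "10M", flag = 0x800L), f))
  expect_false(passes_filters(rec(10, "10M", flag = 0x200L), f))
  expect_false(passes_filters(rec(10, "10M", flag = 0x4L), f))
  expect_true(passes_filters(rec(10, "10M", flag = 0x400L), f))
  expect_false(passes_filters(rec(10, "10M", flag = 0x400L),
                              filter_config(include_duplicates = FALSE)))
  expect_true(passes_filters(rec(10, "10M", flag = 0x100L),
                             filter_config(include_secondary = TRUE)))
  expect_false(passes_filters(rec(10, "10M", mapq = 3L),
                              filter_config(min_mapping_quality = 10)))
  expect_error(filter_config(min_mapping_quality = 300), "\\[0, 255\\]")
})

write_test_sam <- function(records, ref_len = 2000L) {
  dir <- tempfile("samdir")
  dir.create(dir)
  path <- file.path(dir, "t.sam")
  write_sam(records[order(records$pos), , drop = FALSE], reference = NULL,
            path = path, chromosome = records$rname[1],
            reference_length = ref_len)
  path
}

test_that("region queries return exactly the span-overlapping records", {
  nl <- tiny_locus()
  # 3 reads inside the analysis region ([90, 410) with window 10), 2 outside
  inside <- rec(pos = c(120, 250, 380), cigar = c("30M", "20M", "25M"),
                qname = c("in1", "in2", "in3"))
  outside <- rec(pos = c(10, 1500), cigar = c("30M", "40M"),
                 qname = c("out1", "out2"))
  sam <- write_test_sam(rbind(inside, outside))
  got <- read_alignments(sam, nl)
  expect_identical(sort(got$qname), c("in1", "in2", "in3"))
  expect_false(is.unsorted(got$pos))
})

test_that("a read overlapping only via its N skip is still returned", {
  nl <- tiny_locus()
  # aligned blocks at [40,60) and [500,520): both outside the analysis
  # region [90,410), but the skip spans it
  bridge <- rec(40, "20M440N20M", qname = "bridge")
  sam <- write_test_sam(bridge)
  got <- read_alignments(sam, nl)
  expect_identical(got$qname, "bridge")
})

test_that("an empty region yields an empty stream, not an error", {
  nl <- tiny_locus()
  sam <- write_test_sam(rec(1500, "40M", qname = "far"))
  got <- read_alignments(sam, nl)
  expect_identical(nrow(got), 0L)
  # header-only file behaves the same
  empty <- file.path(withr::local_tempdir(), "empty.sam")
  write_sam(alignment_records(), NULL, empty, chromosome = "chr1",
            reference_length = 2000L)
  expect_identical(nrow(read_alignments(empty, nl)), 0L)
})

test_that("region query equals a brute-force span-overlap scan", {
  nl <- tiny_locus()
  for (seed in c(11, 12, 13)) {
    rr <- random_records(120, nl, seed = seed)
    sam <- write_test_sam(rr)
    got <- read_alignments(sam, nl)
    spans <- t(vapply(seq_len(nrow(rr)),
                      function(i) ref_span(rr$pos[i], rr$cigar[i]),
                      numeric(2)))
    ar <- nl$analysis_region
    manual <- rr$qname[spans[, 1] < ar[2] & spans[, 2] > ar[1]]
    expect_setequal(got$qname, manual)
  }
})

test_that("missing BAM index and absent chromosome give clear errors", {
  nl <- tiny_locus()
  sam <- write_test_sam(rec(120, "30M"))
  bam <- suppressMessages(Rsamtools::asBam(
    sam, file.path(dirname(sam), "noidx"), overwrite = TRUE,
    indexDestination = FALSE))
  expect_error(read_alignments(bam, nl), "index")

  other <- tiny_locus()
  other$chromosome <- "chr9"
  expect_error(read_alignments(sam, other), "chr9.*available")
  # dialect matching: plain "1" finds "chr1"
  undialect <- tiny_locus()
  undialect$chromosome <- "1"
  expect_identical(nrow(read_alignments(sam, undialect)), 1L)
  strict <- tiny_locus()
  strict$chromosome <- "1"
  strict$strict_chrom <- TRUE
  expect_error(read_alignments(sam, strict), "available")
})
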