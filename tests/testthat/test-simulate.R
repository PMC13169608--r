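test_that("toy locus construction is deterministic and well-formed", {
  t <- toy_locus()
  b1 <- build_toy_locus(t, seed = 9)
  b2 <- build_toy_locus(t, seed = 9)
  expect_identical(b1$reference, b2$reference)
  expect_true(nchar(b1$reference) >= 3000)
  cfg <- b1$config
  expect_identical(diff(cfg$intron1) + 1L, 2000L)
  # transcript region spans exon1 start through the pseudo-exon end
  expect_identical(cfg$transcript_region,
                   c(t$origin, t$origin + t$exon1_len + t$pseudo_exon[2] - 1L))
  b3 <- build_toy_locus(t, seed = 10)
  expect_false(identical(b1$reference, b3$reference))
  expect_error(toy_locus(pseudo_exon = c(500, 2500)), "pseudo_exon")
  expect_error(toy_locus(pseudo_exon = c(400, 100)), "pseudo_exon")
})

test_that("pure canonical mixtures produce only intron-length skips", {
  t <- toy_locus()
  sim <- simulate_reads(t, simulation_params(mis_fraction = 0,
                                             retained_fraction = 0,
                                             n_reads = 500, seed = 2))
  skips <- regmatches(sim$records$cigar,
                      regexpr("[0-9]+(?=N)", sim$records$cigar, perl = TRUE))
  expect_true(length(skips) > 0)
  expect_true(all(as.integer(skips) == t$intron_len))
  expect_false(any(sim$truth$expected_category == "intron_contained"))
})

test_that("pure retained mixtures have no skips and intronic reads", {
  t <- toy_locus()
  sim <- simulate_reads(t, simulation_params(mis_fraction = 0,
                                             retained_fraction = 1,
                                             n_reads = 500, seed = 3))
  expect_false(any(grepl("N", sim$records$cigar)))
  expect_true(any(sim$truth$expected_category == "intron_contained"))
})

test_that("the classifier reproduces the simulator's truth labels", {
  t <- toy_locus()
  nl <- normalize_locus(toy_locus_config(t))
  for (fr in list(c(0, 0), c(0.5, 0), c(0.3, 0.3), c(0, 1))) {
    sim <- simulate_reads(t, simulation_params(
      mis_fraction = fr[1], retained_fraction = fr[2],
      n_reads = 1500, seed = 11))
    got <- as.character(splicewatch:::classify_records(sim$records, nl))
    expect_identical(got, sim$truth$expected_category)
  }
})

test_that("simulation is reproducible per seed and seeds differ", {
  t <- toy_locus()
  p <- simulation_params(mis_fraction = 0.4, n_reads = 300, seed = 5)
  s1 <- simulate_reads(t, p)
  s2 <- simulate_reads(t, p)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(t, simulation_params(mis_fraction = 0.4,
                                            n_reads = 300, seed = 6))
  expect_false(identical(s1$records$pos, s3$records$pos))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simulation_params(mis_fraction = 0.7, retained_fraction = 0.5),
               "f \\+ r")
  expect_error(simulation_params(mis_fraction = -0.1), "non-negative")
  t <- toy_locus(exon1_len = 60, intron_len = 500, exon2_len = 60,
                 pseudo_exon = c(100, 160))
  # shortest transcript (canonical, 120 bases) is shorter than the read
  expect_error(simulate_reads(t, simulation_params(n_reads = 10)),
               "shortest transcript")
})

test_that("expected PSI is exact at the mixture extremes", {
  t <- toy_locus()
  e <- expected_psi(t, simulation_params(mis_fraction = 0,
                                         retained_fraction = 0))
  expect_identical(e$expected_psi, 0)
  expect_identical(e$expected_intron_rate, 0)
  expect_true(e$expected_junction_rate > 0)
  # all reads retained: no junction source, PSI = 1
  e <- expected_psi(t, simulation_params(mis_fraction = 0,
                                         retained_fraction = 1))
  expect_identical(e$expected_psi, 1)
  expect_identical(e$expected_junction_rate, 0)
})

test_that("expected PSI is non-decreasing in the retained fraction", {
  t <- toy_locus()
  for (f in c(0, 0.2)) {
    psis <- vapply(seq(0, 1 - f, by = 0.2), function(r) {
      e <- expected_psi(t, simulation_params(mis_fraction = f,
                                             retained_fraction = r))
      e$expected_psi
    }, numeric(1))
    expect_true(all(diff(psis) >= -1e-12))
  }
})

test_that("observed category frequencies track the enumeration rates", {
  t <- toy_locus()
  p <- simulation_params(mis_fraction = 0.5, retained_fraction = 0,
                         n_reads = 10000, seed = 1)
  sim <- simulate_reads(t, p)
  n <- nrow(sim$records)
  # cryptic-junction frequency within 3 binomial SE of the exact rate
  rate <- sim$rates$expected_cryptic_rate
  obs <- mean(sim$truth$expected_category == "cryptic_junction")
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(obs - rate), 3 * se)
})

test_that("single-end mode matches its own enumeration", {
  t <- toy_locus()
  p <- simulation_params(mis_fraction = 0.3, retained_fraction = 0.2,
                         n_reads = 8000, paired = FALSE, seed = 13)
  sim <- simulate_reads(t, p)
  expect_identical(nrow(sim$records), 8000L)
  rate <- sim$rates$expected_intron_rate
  obs <- mean(sim$truth$expected_category == "intron_contained")
  se <- sqrt(rate * (1 - rate) / nrow(sim$records))
  expect_lt(abs(obs - rate), 4 * se)
})

test_that("SAM output round-trips through the alignment reader", {
  t <- toy_locus()
  nl <- normalize_locus(toy_locus_config(t))
  dir <- withr::local_tempdir()
  sim <- run_simulate(t, simulation_params(mis_fraction = 0.5,
                                           n_reads = 200, seed = 7),
                      out_dir = dir)
  expect_true(file.exists(sim$paths$sam))
  expect_true(file.exists(sim$paths$reference))
  got <- read_alignments(sim$paths$sam, nl)
  expect_identical(got$pos, sim$records$pos)
  expect_identical(got$cigar, sim$records$cigar)
  expect_identical(got$qname, sim$records$qname)
  # SAM body has one line per record plus the 3 header lines
  lines <- readLines(sim$paths$sam)
  expect_identical(sum(!startsWith(lines, "@")), nrow(sim$records))
  # sequences come from the reference: spot-check one plain M read
  plain <- which(!grepl("N", sim$records$cigar))[1]
  built <- build_toy_locus(t, seed = 7)
  body <- strsplit(lines[!startsWith(lines, "@")][plain], "\t")[[1]]
  expect_identical(body[10],
                   substring(built$reference, as.integer(body[4]),
                             as.integer(body[4]) + 149L))
})

test_that("empty simulations give a readable header-only SAM", {
  t <- toy_locus()
  dir <- withr::local_tempdir()
  sim <- run_simulate(t, simulation_params(n_reads = 0, seed = 1),
                      out_dir = dir)
  nl <- normalize_locus(toy_locus_config(t))
  got <- read_alignments(sim$paths$sam, nl)
  expect_identical(nrow(got), 0L)
  cts <- count_reads(got, nl)
  expect_identical(cts$total, 0L)
})

test_that("unsorted records are refused by the SAM writer", {
  r <- rbind(rec(500, "10M"), rec(100, "10M"))
  expect_error(write_sam(r, NULL, tempfile(), chromosome = "chr1",
                         reference_length = 1000L), "sorted")
})
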