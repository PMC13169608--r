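test_that("PSI and efficiency follow the count formulas", {
  m <- compute_metrics(list(sample_id = "s", junction = 90, intron = 10))
  expect_equal(m$psi, 0.10)
  expect_equal(m$efficiency, 0.90)
  # boundary: all reads intronic
  m <- compute_metrics(list(junction = 0, intron = 25))
  expect_equal(m$psi, 1.0)
  expect_equal(m$efficiency, 0.0)
  # degenerate denominator stays NA, never 0
  m <- compute_metrics(list(junction = 0, intron = 0))
  expect_true(is.na(m$psi) && is.na(m$efficiency))
  expect_true(is.na(m$psi_ci_low) && is.na(m$psi_ci_high))
})

test_that("psi + efficiency is exactly 1 whenever defined", {
  set.seed(5)
  for (i in 1:50) {
    j <- sample(0:500, 1); k <- sample(0:500, 1)
    if (j + k == 0) next
    m <- compute_metrics(list(junction = j, intron = k))
    expect_identical(m$psi + m$efficiency, 1)
  }
})

test_that("PSI is strictly monotone in the intron count", {
  j <- 40L
  psis <- vapply(0:30, function(i)
    compute_metrics(list(junction = j, intron = i))$psi, numeric(1))
  expect_true(all(diff(psis) > 0))
})

test_that("the PSI interval matches the exact binomial interval", {
  for (ji in list(c(90, 10), c(5, 5), c(0, 17), c(33, 0))) {
    m <- compute_metrics(list(junction = ji[1], intron = ji[2]))
    bt <- binom.test(ji[2], sum(ji))$conf.int
    expect_equal(c(m$psi_ci_low, m$psi_ci_high), as.numeric(bt),
                 tolerance = 1e-12)
  }
})

test_that("the two-sided Fisher p equals exhaustive enumeration", {
  # 61 attainable tables for these margins; the oracle enumerates them all
  ft <- fisher_exact_two_sided(rbind(c(10, 90), c(50, 50)))
  expect_lt(abs(ft$p_value - enum_fisher_p(10, 90, 50, 50)), 1e-12)
  expect_equal(ft$odds_ratio, (10 * 50) / (90 * 50))
  # symmetric modal table
  expect_equal(fisher_exact_two_sided(rbind(c(5, 5), c(5, 5)))$p_value, 1.0)
  # degenerate column: a single attainable table
  ft <- fisher_exact_two_sided(rbind(c(0, 10), c(0, 20)))
  expect_equal(ft$p_value, 1.0)
  expect_true(is.na(ft$odds_ratio))
  expect_error(fisher_exact_two_sided(rbind(c(0, 0), c(0, 0))), "all-zero")
  # infinite odds ratio when the off-diagonal is empty
  expect_identical(fisher_exact_two_sided(rbind(c(5, 0), c(0, 5)))$odds_ratio,
                   Inf)
})

test_that("Fisher p agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:100) {
    tab <- matrix(sample(0:60, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_two_sided(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher p lies in (0,1] and is invariant under joint swaps", {
  set.seed(19)
  for (i in 1:50) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)$p_value
    expect_true(p > 0 && p <= 1)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_two_sided(swapped)$p_value, p,
                 tolerance = 1e-14)
  }
})

test_that("group comparisons cover all pairs and respect direction", {
  groups <- list(
    A = list(canonical_junction = 900L, intron_contained = 100L),
    B = list(canonical_junction = 500L, intron_contained = 500L),
    C = list(canonical_junction = 880L, intron_contained = 120L))
  res <- compare_groups(groups)
  expect_identical(nrow(res), 3L)
  ab <- res[res$group_a == "A" & res$group_b == "B", ]
  expect_equal(ab$p_value, enum_fisher_p(900, 100, 500, 500),
               tolerance = 1e-12)
  psi_a <- 100 / 1000; psi_b <- 500 / 1000
  expect_true(psi_b > psi_a)
  expect_true(ab$odds_ratio > 1)  # junction odds higher in A

  # identical pooled counts give p = 1
  same <- compare_groups(list(X = list(junction = 10, intron = 5),
                              Y = list(junction = 10, intron = 5)))
  expect_equal(same$p_value, 1.0)
})

test_that("a zero-information group is flagged, others unaffected", {
  groups <- list(
    silenced = list(junction = 0L, intron = 0L),
    ctrl = list(junction = 90L, intron = 10L),
    fxs = list(junction = 40L, intron = 60L))
  res <- compare_groups(groups)
  expect_identical(nrow(res), 3L)
  dead <- res[res$group_a == "silenced" | res$group_b == "silenced", ]
  expect_true(all(!dead$testable))
  expect_true(all(is.na(dead$p_value)))
  live <- res[res$testable, ]
  expect_identical(nrow(live), 1L)
  expect_false(is.na(live$p_value))
})

test_that("replicate pooling is consistent and adjustment never lowers p", {
  groups <- list(
    A = data.frame(canonical_junction = c(400L, 500L),
                   intron_contained = c(50L, 50L)),
    B = list(junction = 300L, intron = 300L),
    C = list(junction = 200L, intron = 100L))
  raw <- compare_groups(groups)
  for (method in c("bonferroni", "bh")) {
    adj <- compare_groups(groups, adjust = method)
    expect_true(all(adj$adjusted_p >= adj$p_value - 1e-15))
    expect_equal(adj$p_value, raw$p_value)
  }
  # pooling: group A is the sum of its replicate rows
  expect_identical(raw$junction_a[raw$group_a == "A"][1], 900L)
})

test_that("replicate summaries use defined values and the n-1 SD", {
  mk <- function(j, i) compute_metrics(list(junction = j, intron = i))
  reps <- list(mk(90, 10), mk(88, 12), mk(92, 8), mk(90, 10))
  s <- summarize_replicates(reps, "grp")
  expect_equal(s$mean_psi, mean(c(0.10, 0.12, 0.08, 0.10)))
  expect_equal(s$sd_psi, sd(c(0.10, 0.12, 0.08, 0.10)))
  expect_identical(s$n_undefined, 0L)

  single <- summarize_replicates(list(mk(50, 50)), "one")
  expect_equal(single$mean_psi, 0.5)
  expect_true(is.na(single$sd_psi))

  with_na <- summarize_replicates(list(mk(90, 10), mk(0, 0), mk(88, 12),
                                       mk(92, 8)), "partial")
  expect_identical(with_na$n_undefined, 1L)
  expect_equal(with_na$mean_psi, mean(c(0.10, 0.12, 0.08)))

  all_na <- summarize_replicates(list(mk(0, 0), mk(0, 0)), "dead")
  expect_true(is.na(all_na$mean_psi))
  expect_identical(all_na$n_undefined, 2L)
})

test_that("pooled PSI lies within the range of per-replicate PSIs", {
  set.seed(23)
  for (i in 1:30) {
    j <- sample(1:200, 4); k <- sample(1:200, 4)
    per <- k / (j + k)
    pooled <- sum(k) / (sum(j) + sum(k))
    expect_true(pooled >= min(per) - 1e-12 && pooled <= max(per) + 1e-12)
  }
})
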