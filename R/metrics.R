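#' Intron-retention PSI and splicing efficiency for one sample
#'
#' Percent-spliced-in is the fraction of informative reads supporting
#' intron retention, `PSI = intron / (junction + intron)`; splicing
#' efficiency is its complement, `junction / (junction + intron)`. Only
#' canonical-junction and intron-contained reads are informative:
#' cryptic-junction reads support neither term and are reported separately.
#' When no informative reads exist (a transcriptionally silenced locus)
#' both quantities are undefined and returned as `NA` — never coerced to
#' zero, so silence stays distinguishable from perfect splicing.
#'
#' @param counts A `read_class_counts` row from [count_reads()], or any
#'   list with `canonical_junction` and `intron_contained` (a plain
#'   `junction` / `intron` pair is also accepted).
#' @param conf_level Confidence level for the Clopper-Pearson (exact
#'   binomial) interval on PSI, default 0.95.
#' @return An object of class `splicing_metrics`: a one-row data frame with
#'   `sample_id`, `junction`, `intron`, `psi`, `efficiency`, `psi_ci_low`,
#'   `psi_ci_high`.
#' @examples
#' compute_metrics(list(sample_id = "s1", junction = 90, intron = 10))
#' @export
compute_metrics <- function(counts, conf_level = 0.95) {
  j <- if (!is.null(counts$canonical_junction))
    counts$canonical_junction else counts$junction
  i <- if (!is.null(counts$intron_contained))
    counts$intron_contained else counts$intron
  if (is.null(j) || is.null(i))
    stop("counts must carry junction and intron read counts", call. = FALSE)
  j <- as.integer(j); i <- as.integer(i)
  stopifnot(j >= 0L, i >= 0L)
  n <- j + i
  if (n == 0L) {
    psi <- eff <- lo <- hi <- NA_real_
  } else {
    psi <- i / n
    eff <- j / n
    ci <- clopper_pearson(i, n, conf_level)
    lo <- ci[1]; hi <- ci[2]
  }
  out <- data.frame(
    sample_id = if (!is.null(counts$sample_id)) counts$sample_id else "sample",
    junction = j, intron = i, psi = psi, efficiency = eff,
    psi_ci_low = lo, psi_ci_high = hi, stringsAsFactors = FALSE)
  class(out) <- c("splicing_metrics", "data.frame")
  out
}

# exact binomial interval; the standard beta-quantile form
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

# Two-sided Fisher p-values for every attainable cell value a given the
# margins (m = column-1 total, n = column-2 total, k = row-1 total).
# Returns p for a = max(0, k - n) .. min(k, m). Two-sided rule: sum the
# hypergeometric point probabilities of all tables no more probable than
# the observed one. A relative tolerance guards the <= comparison against
# floating-point ties between equally probable tables.
fisher_p_support <- function(m, n, k, rel_tol = 1 + 1e-7) {
  x <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(x, m, n, k)
  ds <- sort(d)
  cs <- cumsum(ds)
  pmin(1, cs[findInterval(d * rel_tol, ds)])
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on the table margins, the two-sided p-value sums the
#' hypergeometric point probabilities of every table whose probability does
#' not exceed that of the observed table (the point-probability rule, the
#' convention used by standard exact-test implementations). The odds ratio
#' is the sample odds ratio `(a*d)/(b*c)`: `Inf` when `b*c == 0` with
#' `a*d > 0`, `NA` for the indeterminate `0/0`.
#'
#' @param table A 2x2 matrix of non-negative counts,
#'   `rbind(c(a, b), c(c, d))`; rows are groups, columns are junction /
#'   intron reads.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_two_sided(rbind(c(10, 90), c(50, 50)))
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0) || anyNA(tab))
    stop("table cells must be non-negative counts", call. = FALSE)
  if (sum(tab) < 1)
    stop("cannot test an all-zero table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + cc; n <- b + d; k <- a + b
  p_all <- fisher_p_support(m, n, k)
  x <- max(0L, k - n):min(k, m)
  p <- p_all[match(a, x)]
  or <- if (b * cc > 0) (a * d) / (b * cc)
        else if (a * d > 0) Inf
        else NA_real_
  list(odds_ratio = or, p_value = p)
}

#' Pairwise Fisher comparisons of pooled group counts
#'
#' Builds one 2x2 table per unordered pair of groups from their pooled
#' canonical-junction and intron-contained counts and applies
#' [fisher_exact_two_sided()]. A group with no informative reads renders
#' its pairs not testable (`p_value = NA`, flagged) without affecting the
#' rest.
#'
#' @param groups A named list: `group_id -> read_class_counts` (or any list
#'   with `canonical_junction`/`junction` and `intron_contained`/`intron`).
#'   Multi-row counts are summed, i.e. replicates are pooled.
#' @param adjust Multiple-testing adjustment over the pair set: `"none"`
#'   (default, raw p-values), `"bonferroni"` or `"bh"`
#'   (Benjamini-Hochberg).
#' @return A data frame of class `comparison_results`, one row per pair:
#'   `group_a`, `group_b`, `junction_a`, `intron_a`, `junction_b`,
#'   `intron_b`, `odds_ratio`, `p_value`, `adjusted_p`, `method`,
#'   `testable`.
#' @export
compare_groups <- function(groups, adjust = c("none", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L)
    stop("need at least two groups to compare", call. = FALSE)
  ids <- names(groups)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("groups must be a named list", call. = FALSE)
  pick <- function(g, primary, alias) {
    v <- if (!is.null(g[[primary]])) g[[primary]] else g[[alias]]
    if (is.null(v)) stop("group lacks ", primary, " counts", call. = FALSE)
    sum(as.integer(v))
  }
  jx <- vapply(groups, pick, integer(1),
               primary = "canonical_junction", alias = "junction")
  ix <- vapply(groups, pick, integer(1),
               primary = "intron_contained", alias = "intron")
  pairs <- utils::combn(seq_along(ids), 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    testable <- (jx[i] + ix[i]) > 0L && (jx[j] + ix[j]) > 0L
    if (testable) {
      ft <- fisher_exact_two_sided(rbind(c(jx[i], ix[i]), c(jx[j], ix[j])))
    } else {
      ft <- list(odds_ratio = NA_real_, p_value = NA_real_)
    }
    data.frame(group_a = ids[i], group_b = ids[j],
               junction_a = jx[i], intron_a = ix[i],
               junction_b = jx[j], intron_b = ix[j],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               testable = testable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- if (adjust == "none") NA_real_ else
    stats::p.adjust(res$p_value,
                    method = c(bonferroni = "bonferroni", bh = "BH")[adjust])
  res$method <- paste0("fisher_exact_two_sided",
                       if (adjust != "none") paste0("+", adjust) else "")
  class(res) <- c("comparison_results", "data.frame")
  res
}

#' Summarize per-replicate splicing metrics for a group
#'
#' Mean and standard deviation (n-1 denominator) of PSI and splicing
#' efficiency over the replicates whose metrics are defined; replicates
#' with undefined PSI (no informative reads) are excluded and counted.
#'
#' @param per_replicate A list of [compute_metrics()] results, or a
#'   multi-row `splicing_metrics` data frame.
#' @param group_id Group label.
#' @return A one-row data frame of class `replicate_summary`: `group_id`,
#'   `n_replicates`, `n_undefined`, `mean_psi`, `sd_psi`,
#'   `mean_efficiency`, `sd_efficiency`.
#' @export
summarize_replicates <- function(per_replicate, group_id = "group") {
  df <- if (is.data.frame(per_replicate)) per_replicate
        else do.call(rbind, per_replicate)
  if (nrow(df) < 1L)
    stop("need at least one replicate", call. = FALSE)
  ok <- !is.na(df$psi)
  n_def <- sum(ok)
  out <- data.frame(
    group_id = group_id,
    n_replicates = nrow(df),
    n_undefined = nrow(df) - n_def,
    mean_psi = if (n_def) mean(df$psi[ok]) else NA_real_,
    sd_psi = if (n_def >= 2) stats::sd(df$psi[ok]) else NA_real_,
    mean_efficiency = if (n_def) mean(df$efficiency[ok]) else NA_real_,
    sd_efficiency = if (n_def >= 2) stats::sd(df$efficiency[ok])
                    else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' Write splicing metrics as TSV
#' @param metrics A `splicing_metrics` data frame (rows may span samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(as.data.frame(metrics), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write pairwise comparison results as TSV
#'
#' Adds a `stars` column at the conventional thresholds (`*` < 0.05,
#' `**` < 0.01, `***` < 0.001) computed from the raw p-value.
#'
#' @param comparisons A `comparison_results` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparisons_tsv <- function(comparisons, path) {
  df <- as.data.frame(comparisons)
  df$stars <- significance_stars(df$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
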