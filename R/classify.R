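#' Classifier settings for junction matching
#'
#' @param junction_match `"windowed"` (default): a skip boundary matches a
#'   splice site when it falls within `window_bp` bases of it, tolerating
#'   minor alignment jitter; `"exact"`: the skip must coincide with the
#'   intron exactly. Cryptic-junction detection always uses the window at
#'   the donor side and requires the acceptor to land strictly inside the
#'   intron, beyond the acceptor window.
#' @param min_overhang_bp Minimum aligned bases required on each side of a
#'   junction-defining skip (default 1, the weakest rule consistent with
#'   "spanning" the junction).
#' @param window_bp Override of the locus window width; `NULL` (default)
#'   inherits `window_bp` from the locus configuration.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(junction_match = c("windowed", "exact"),
                              min_overhang_bp = 1L, window_bp = NULL) {
  junction_match <- match.arg(junction_match)
  ov <- as.integer(min_overhang_bp)[1]
  if (is.na(ov) || ov < 1L)
    stop("min_overhang_bp must be >= 1", call. = FALSE)
  structure(list(junction_match = junction_match,
                 min_overhang_bp = ov,
                 window_bp = if (is.null(window_bp)) NULL
                             else as.integer(window_bp)[1]),
            class = "classifier_config")
}

READ_CATEGORIES <- c("canonical_junction", "cryptic_junction",
                     "intron_contained", "unclassified")

effective_window <- function(locus, cfg) {
  if (!is.null(cfg$window_bp)) cfg$window_bp else locus$window_bp
}

# Vectorized classification of a record table against a normalized locus.
# Rules, first match wins:
#   1. canonical_junction: some N skip matches the intron (exactly, or with
#      both boundaries within the window), with >= min_overhang aligned
#      bases flanking that skip.
#   2. cryptic_junction: some N skip starts within the donor window but
#      ends strictly inside the intron short of the acceptor window
#      (exon1 -> pseudo-exon signature), same overhang requirement.
#   3. intron_contained: no N operation and every aligned block inside the
#      intron.
#   4. unclassified.
classify_records <- function(rec, locus, cfg = classifier_config()) {
  n <- nrow(rec)
  out <- factor(rep("unclassified", n), levels = READ_CATEGORIES)
  if (n == 0L) return(out)
  W <- effective_window(locus, cfg)
  donor <- locus$donor_site
  acceptor <- locus$acceptor_site

  blocks <- aligned_blocks_list(rec$pos, rec$cigar)
  has_n <- grepl("N", rec$cigar, fixed = TRUE)

  canon <- logical(n)
  cryptic <- logical(n)
  if (any(has_n)) {
    idx_n <- which(has_n)
    skips <- skipped_intervals_list(rec$pos[idx_n], rec$cigar[idx_n])
    n_sk <- S4Vectors::elementNROWS(skips)
    sk_rec <- idx_n[rep(seq_along(skips), n_sk)]
    sk <- BiocGenerics::unlist(skips, use.names = FALSE)
    s0 <- IRanges::start(sk) - 1L          # 0-based skip start
    e0 <- IRanges::end(sk)                 # half-open skip end

    # overhang: width of the aligned block flanking the skip on each side.
    # Blocks are maximal reference-consuming runs, so in a well-formed
    # CIGAR the j-th skip of a record sits between blocks j and j+1; the
    # adjacency check below catches degenerate CIGARs (leading/trailing or
    # back-to-back N), which then get overhang 0.
    bl <- blocks[idx_n]
    n_bl <- S4Vectors::elementNROWS(bl)
    bl_all <- BiocGenerics::unlist(bl, use.names = FALSE)
    b_s0 <- IRanges::start(bl_all) - 1L
    b_e0 <- IRanges::end(bl_all)
    b_w <- IRanges::width(bl_all)
    bl_off <- cumsum(c(0L, n_bl[-length(n_bl)]))      # per idx_n record
    sk_local <- sequence(n_sk)                        # j within record
    sk_of <- rep(seq_along(n_sk), n_sk)               # idx_n-local record
    safe <- function(v, i, valid) {
      out <- rep(NA_integer_, length(i))
      out[valid] <- v[i[valid]]
      out
    }
    left_i <- bl_off[sk_of] + sk_local
    right_i <- left_i + 1L
    lv <- sk_local <= n_bl[sk_of]
    rv <- sk_local + 1L <= n_bl[sk_of]
    left_ok <- lv & safe(b_e0, left_i, lv) == s0
    right_ok <- rv & safe(b_s0, right_i, rv) == e0
    left_ov <- ifelse(left_ok %in% TRUE, safe(b_w, left_i, lv), 0L)
    right_ov <- ifelse(right_ok %in% TRUE, safe(b_w, right_i, rv), 0L)
    ov_ok <- left_ov >= cfg$min_overhang_bp & right_ov >= cfg$min_overhang_bp

    canon_skip <- if (cfg$junction_match == "exact")
      s0 == donor & e0 == acceptor
    else
      abs(s0 - donor) <= W & abs(e0 - acceptor) <= W
    cryptic_skip <- abs(s0 - donor) <= W &
      e0 > donor & e0 < acceptor - W
    canon[unique(sk_rec[canon_skip & ov_ok])] <- TRUE
    cryptic[unique(sk_rec[cryptic_skip & ov_ok])] <- TRUE
  }

  rng <- range(blocks)                    # one range (or none) per record
  n_rng <- S4Vectors::elementNROWS(rng)
  flat <- BiocGenerics::unlist(rng, use.names = FALSE)
  b_min <- rep(NA_integer_, n)
  b_max <- rep(NA_integer_, n)
  b_min[n_rng == 1L] <- IRanges::start(flat) - 1L
  b_max[n_rng == 1L] <- IRanges::end(flat)
  contained <- !has_n & !is.na(b_min) & b_min >= donor & b_max <= acceptor

  out[contained] <- "intron_contained"
  out[cryptic] <- "cryptic_junction"
  out[canon] <- "canonical_junction"       # rule 1 overrides all
  out
}

#' Classify a single alignment record
#'
#' Assigns exactly one of `canonical_junction`, `cryptic_junction`,
#' `intron_contained`, `unclassified` by the first matching rule (see
#' [classifier_config()] and the package vignette for the rule definitions).
#'
#' @param rec A one-row [alignment_records()] data frame; must be mapped
#'   and overlap the locus analysis region.
#' @param locus A `normalized_locus`.
#' @param cfg A [classifier_config()].
#' @return A length-1 character: the category.
#' @export
classify_read <- function(rec, locus, cfg = classifier_config()) {
  if (nrow(rec) != 1L)
    stop("classify_read expects exactly one record; use count_reads() for ",
         "tables", call. = FALSE)
  if (has_flag(rec$flag, FLAG_UNMAPPED) || rec$cigar == "*")
    stop("contract violation: record is unmapped", call. = FALSE)
  span_end <- rec$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  ar <- locus$analysis_region
  if (span_end <= ar[1] || rec$pos >= ar[2])
    stop("contract violation: record does not overlap the analysis region",
         call. = FALSE)
  as.character(classify_records(rec, locus, cfg))
}

#' Count reads per splicing category
#'
#' Applies the record filters, classifies every passing record and tallies
#' the four categories. With `count_mode = "per_fragment"` the records of a
#' fragment (same query name) are collapsed to one count: the shared
#' category if all mates agree, otherwise `unclassified`.
#'
#' @param records An [alignment_records()] data frame (e.g. from
#'   [read_alignments()]).
#' @param locus A `normalized_locus`.
#' @param fcfg A [filter_config()].
#' @param ccfg A [classifier_config()].
#' @param sample_id Sample label carried into the result.
#' @return An object of class `read_class_counts`: a one-row data frame
#'   with columns `sample_id`, `canonical_junction`, `cryptic_junction`,
#'   `intron_contained`, `unclassified`, `total`.
#' @export
count_reads <- function(records, locus, fcfg = filter_config(),
                        ccfg = classifier_config(), sample_id = "sample") {
  keep <- if (nrow(records)) passes_filters(records, fcfg) else logical(0)
  rec <- records[keep, , drop = FALSE]
  cats <- classify_records(rec, locus, ccfg)
  if (fcfg$count_mode == "per_fragment" && nrow(rec)) {
    agg <- tapply(as.character(cats), rec$qname, function(x)
      if (length(unique(x)) == 1L) x[1] else "unclassified")
    cats <- factor(unname(agg), levels = READ_CATEGORIES)
  }
  tab <- table(cats)
  out <- data.frame(sample_id = sample_id,
                    canonical_junction = as.integer(tab["canonical_junction"]),
                    cryptic_junction = as.integer(tab["cryptic_junction"]),
                    intron_contained = as.integer(tab["intron_contained"]),
                    unclassified = as.integer(tab["unclassified"]),
                    stringsAsFactors = FALSE)
  out$total <- out$canonical_junction + out$cryptic_junction +
    out$intron_contained + out$unclassified
  class(out) <- c("read_class_counts", "data.frame")
  out
}

#' Write per-sample category counts as TSV
#'
#' @param counts A `read_class_counts` data frame (rows may be rbind-ed
#'   across samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
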