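#' Per-base read coverage over a region
#'
#' Depth at each base is the number of filtered records whose aligned
#' blocks (`M`, `=`, `X` runs) cover it. `N`-skipped stretches, deletions
#' and clipped bases contribute nothing, so a spliced read leaves a gap
#' across the intron it skips.
#'
#' @param records An [alignment_records()] data frame.
#' @param region 0-based half-open `c(start, end)`.
#' @param fcfg A [filter_config()].
#' @param sample_id Sample label.
#' @param chromosome Chromosome name stored with the track (taken from the
#'   records when omitted).
#' @return An object of class `coverage_track`: a list with `sample_id`,
#'   `chromosome`, `region`, `depth` (numeric vector of length
#'   `region[2] - region[1]`), `scaled` (FALSE) and `scale_factor` (NA).
#' @export
compute_coverage <- function(records, region, fcfg = filter_config(),
                             sample_id = "sample", chromosome = NULL) {
  region <- as.integer(region)
  stopifnot(length(region) == 2L, region[1] <= region[2])
  width <- region[2] - region[1]
  keep <- if (nrow(records)) passes_filters(records, fcfg) else logical(0)
  rec <- records[keep, , drop = FALSE]
  depth <- numeric(width)
  if (nrow(rec)) {
    # base-aligned ops only: D consumes reference but carries no read base
    bl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      rec$cigar, pos = rec$pos + 1L, ops = c("M", "=", "X"),
      drop.empty.ranges = TRUE)
    ir <- BiocGenerics::unlist(bl, use.names = FALSE)   # 1-based closed
    ir <- IRanges::restrict(ir, start = region[1] + 1L, end = region[2])
    if (length(ir) && width > 0L) {
      cov <- IRanges::coverage(IRanges::shift(ir, -region[1]),
                               width = width)
      depth <- as.numeric(cov)
    }
  }
  if (is.null(chromosome))
    chromosome <- if (nrow(rec)) rec$rname[1] else NA_character_
  structure(list(sample_id = sample_id, chromosome = chromosome,
                 region = region, depth = depth, scaled = FALSE,
                 scale_factor = NA_real_),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track '", x$sample_id, "' ", x$chromosome, ":[",
      x$region[1], ", ", x$region[2], ")  max depth ",
      if (length(x$depth)) max(x$depth) else 0,
      if (x$scaled) sprintf(" (scaled by %g)", x$scale_factor) else "",
      "\n", sep = "")
  invisible(x)
}

#' Scale a pair of coverage tracks to their joint maximum
#'
#' Both tracks are divided by the single pair-wide maximum raw depth, so
#' the deeper track peaks at 1.0 and the two are directly comparable in a
#' browser. If neither track has coverage the pair is returned unscaled
#' and flagged.
#'
#' @param a,b `coverage_track` objects over the same region.
#' @return A list of the two tracks (`a`, `b`), scaled unless degenerate.
#' @export
scale_pair <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  if (!identical(a$region, b$region))
    stop("cannot scale tracks over different regions", call. = FALSE)
  peak <- max(c(a$depth, b$depth, 0))
  if (peak == 0) {
    a$scaled <- b$scaled <- FALSE
    a$scale_factor <- b$scale_factor <- NA_real_
    return(list(a = a, b = b, degenerate = TRUE))
  }
  rescale <- function(tr) {
    tr$depth <- tr$depth / peak
    tr$scaled <- TRUE
    tr$scale_factor <- peak
    tr
  }
  list(a = rescale(a), b = rescale(b), degenerate = FALSE)
}

#' Tabulate splice-junction read support (sashimi-style counts)
#'
#' Aggregates every `N`-derived skipped interval of the filtered records
#' into `(donor, acceptor, count)` rows and labels each junction:
#' `canonical` when the skip satisfies the canonical window rule of the
#' locus, `cryptic` when the donor matches but the acceptor lands strictly
#' inside the intron beyond the acceptor window, `other` otherwise.
#' Labels apply the same windows as the read classifier; the per-read
#' overhang requirement does not apply to the aggregate table.
#'
#' @param records An [alignment_records()] data frame.
#' @param locus A `normalized_locus`.
#' @param fcfg A [filter_config()].
#' @param ccfg A [classifier_config()].
#' @param sample_id Sample label.
#' @return A data frame of class `junction_table`: `sample_id`,
#'   `chromosome`, `donor`, `acceptor` (0-based half-open skip bounds),
#'   `count`, `label`; empty when no spliced reads exist.
#' @export
junction_counts <- function(records, locus, fcfg = filter_config(),
                            ccfg = classifier_config(),
                            sample_id = "sample") {
  keep <- if (nrow(records)) passes_filters(records, fcfg) else logical(0)
  rec <- records[keep, , drop = FALSE]
  empty <- data.frame(sample_id = character(), chromosome = character(),
                      donor = integer(), acceptor = integer(),
                      count = integer(), label = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("junction_table", "data.frame")
  if (!nrow(rec)) return(empty)
  has_n <- grepl("N", rec$cigar, fixed = TRUE)
  if (!any(has_n)) return(empty)
  sk <- skipped_intervals_list(rec$pos[has_n], rec$cigar[has_n])
  flat <- BiocGenerics::unlist(sk, use.names = FALSE)
  s0 <- IRanges::start(flat) - 1L
  e0 <- IRanges::end(flat)
  agg <- stats::aggregate(list(count = rep(1L, length(s0))),
                          by = list(donor = s0, acceptor = e0), FUN = sum)
  agg <- agg[order(agg$donor, agg$acceptor), , drop = FALSE]
  W <- effective_window(locus, ccfg)
  donor_site <- locus$donor_site
  acceptor_site <- locus$acceptor_site
  canonical <- if (ccfg$junction_match == "exact")
    agg$donor == donor_site & agg$acceptor == acceptor_site
  else
    abs(agg$donor - donor_site) <= W &
      abs(agg$acceptor - acceptor_site) <= W
  cryptic <- !canonical & abs(agg$donor - donor_site) <= W &
    agg$acceptor > donor_site & agg$acceptor < acceptor_site - W
  out <- data.frame(sample_id = sample_id,
                    chromosome = locus$chromosome,
                    donor = agg$donor, acceptor = agg$acceptor,
                    count = as.integer(agg$count),
                    label = ifelse(canonical, "canonical",
                                   ifelse(cryptic, "cryptic", "other")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("junction_table", "data.frame")
  out
}

#' Write a coverage track as bedGraph
#'
#' Output is 0-based half-open with run-length merged rows; zero-depth runs
#' are omitted, the genome-browser convention.
#'
#' @param track A `coverage_track`.
#' @param path Output path (conventionally `.bedGraph`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    rep(track$chromosome, sum(keep)),
    IRanges::IRanges(start = track$region[1] + starts[keep] + 1L,
                     end = track$region[1] + ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a junction table as TSV (and optionally BED12)
#'
#' The plain TSV has columns `chromosome`, `donor`, `acceptor`, `count`,
#' `label` (plus `sample_id`). The optional BED12 companion encodes each
#' junction as a two-block feature with 1 bp anchors flanking the skip,
#' the layout produced by split-read junction extractors, loadable in
#' genome browsers.
#'
#' @param junctions A `junction_table`.
#' @param path Output TSV path.
#' @param bed12_path Optional BED12 output path.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(junctions, path, bed12_path = NULL) {
  utils::write.table(as.data.frame(junctions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed12_path)) {
    j <- as.data.frame(junctions)
    if (nrow(j)) {
      start <- j$donor - 1L                     # 1 bp anchor before skip
      end <- j$acceptor + 1L                    # 1 bp anchor after skip
      bed <- data.frame(chrom = j$chromosome, chromStart = start,
                        chromEnd = end,
                        name = sprintf("JUNC%05d_%s", seq_len(nrow(j)),
                                       j$label),
                        score = j$count, strand = ".",
                        thickStart = start, thickEnd = end,
                        itemRgb = "0,0,0", blockCount = 2L,
                        blockSizes = "1,1",
                        blockStarts = paste(0L, end - start - 1L, sep = ","),
                        stringsAsFactors = FALSE)
      utils::write.table(bed, bed12_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      file.create(bed12_path)
    }
  }
  invisible(path)
}
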