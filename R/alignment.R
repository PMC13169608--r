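#' Record-level filter settings
#'
#' Controls which alignment records enter counting and how paired records are
#' tallied. Defaults are deliberately permissive — no mapping-quality
#' threshold and duplicates kept — mirroring a plain samtools-style
#' extraction; tighten them for sensitivity analyses.
#'
#' @param min_mapping_quality Minimum MAPQ (0-255); records below are
#'   dropped. Default 0 (no filter).
#' @param include_duplicates Keep PCR/optical duplicate records (default
#'   TRUE).
#' @param include_secondary Keep secondary alignments (default FALSE).
#' @param include_supplementary Keep supplementary alignments (default
#'   FALSE).
#' @param count_mode `"per_record"` (each mate counted independently, the
#'   default) or `"per_fragment"` (a read pair counted once; mates that
#'   disagree are counted as unclassified).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mapping_quality = 0L,
                          include_duplicates = TRUE,
                          include_secondary = FALSE,
                          include_supplementary = FALSE,
                          count_mode = c("per_record", "per_fragment")) {
  count_mode <- match.arg(count_mode)
  mq <- as.integer(min_mapping_quality)[1]
  if (is.na(mq) || mq < 0L || mq > 255L)
    stop("min_mapping_quality must be in [0, 255]", call. = FALSE)
  structure(list(min_mapping_quality = mq,
                 include_duplicates = isTRUE(include_duplicates),
                 include_secondary = isTRUE(include_secondary),
                 include_supplementary = isTRUE(include_supplementary),
                 count_mode = count_mode),
            class = "filter_config")
}

# SAM flag bits
FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L; FLAG_REVERSE <- 0x10L; FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L; FLAG_SECOND <- 0x80L; FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L; FLAG_DUPLICATE <- 0x400L; FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Construct a table of alignment records
#'
#' The in-memory record representation is a plain data frame with one row
#' per alignment record: `qname`, `flag` (SAM bitfield), `rname`, `pos`
#' (0-based leftmost aligned coordinate), `mapq`, `cigar`. This is the
#' currency passed between [read_alignments()], the classifier and the
#' track builders.
#'
#' @param qname,flag,rname,pos,mapq,cigar Per-record vectors, recycled to a
#'   common length.
#' @param ... Further per-record columns carried along untouched (e.g.
#'   `tlen`, `pnext` for SAM output).
#' @return A `data.frame` of class `alignment_records`.
#' @export
alignment_records <- function(qname = character(), flag = 0L,
                              rname = character(), pos = integer(),
                              mapq = 255L, cigar = character(), ...) {
  cols <- list(qname = as.character(qname), flag = as.integer(flag),
               rname = as.character(rname), pos = as.integer(pos),
               mapq = as.integer(mapq), cigar = as.character(cigar), ...)
  n <- max(lengths(cols[c("qname", "pos", "cigar")]))
  df <- do.call(data.frame,
                c(lapply(cols, function(x)
                    if (n == 0L) x[0] else rep_len(x, n)),
                  stringsAsFactors = FALSE))
  if (nrow(df) && any(df$pos < 0L, na.rm = TRUE))
    stop("alignment positions must be >= 0 (0-based)", call. = FALSE)
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Parse a CIGAR string into its operation list
#'
#' @param text A single CIGAR string, or `"*"` for the unmapped convention.
#' @return A data frame with columns `op` (one of `M I D N S H P = X`) and
#'   `length`; zero rows for `"*"`.
#' @examples
#' parse_cigar("100M9703N50M")
#' @export
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(op = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (text == "*") return(empty)
  toks_l <- gregexpr("[0-9]+[MIDNSHP=X]", text)
  toks <- toks_l[[1]]
  consumed <- if (toks[1] == -1L) 0L else {
    ends <- toks + attr(toks, "match.length") - 1L
    # tokens must tile the string from the start with no gaps
    ok <- toks[1] == 1L && all(diff(c(0L, ends)) ==
                               attr(toks, "match.length"))
    if (ok) ends[length(ends)] else {
      gap <- which(c(toks[1] != 1L,
                     toks[-1] != ends[-length(ends)] + 1L))[1]
      if (gap == 1L) 0L else ends[gap - 1L]
    }
  }
  if (consumed != nchar(text))
    stop("malformed CIGAR '", text, "': parse error at offset ",
         consumed + 1L, call. = FALSE)
  pieces <- regmatches(text, toks_l)[[1]]
  data.frame(op = gsub("[0-9]", "", pieces),
             length = as.integer(gsub("[A-Z=]", "", pieces)),
             stringsAsFactors = FALSE)
}

# Vectorized block extraction. Returns an IRangesList (1-based closed, the
# IRanges convention); callers converting to 0-based half-open subtract one
# from start only. D is reference-consuming so it merges into the flanking
# M run; N splits blocks.
aligned_blocks_list <- function(pos0, cigar) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos0 + 1L, ops = c("M", "=", "X", "D"),
    drop.empty.ranges = TRUE, reduce.ranges = TRUE)
}

skipped_intervals_list <- function(pos0, cigar) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos0 + 1L, ops = "N", drop.empty.ranges = TRUE)
}

#' Reference intervals covered by the aligned bases of one record
#'
#' One interval per maximal run of reference-consuming aligned operations
#' (`M`, `=`, `X`; a deletion `D` merges into its enclosing block, an `N`
#' skip splits blocks). Soft/hard clips consume no reference.
#'
#' @param rec A one-row [alignment_records()] data frame (or a list with
#'   `pos` and `cigar`).
#' @return An integer matrix with columns `start`, `end`; 0-based half-open,
#'   disjoint, ascending.
#' @export
aligned_blocks <- function(rec) {
  if (has_flag(rec$flag[1], FLAG_UNMAPPED) || rec$cigar[1] == "*")
    stop("aligned_blocks requires a mapped record", call. = FALSE)
  ir <- aligned_blocks_list(rec$pos[1], rec$cigar[1])[[1]]
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Reference intervals skipped by `N` operations of one record
#'
#' @param rec A one-row [alignment_records()] data frame.
#' @return An integer matrix with columns `start`, `end`; 0-based half-open,
#'   in genomic order; zero rows when the CIGAR has no `N`.
#' @export
skipped_intervals <- function(rec) {
  if (has_flag(rec$flag[1], FLAG_UNMAPPED) || rec$cigar[1] == "*")
    stop("skipped_intervals requires a mapped record", call. = FALSE)
  ir <- skipped_intervals_list(rec$pos[1], rec$cigar[1])[[1]]
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Test records against a filter configuration
#'
#' A record passes unless it is unmapped, QC-fail, a secondary /
#' supplementary / duplicate record that the config excludes, or below the
#' mapping-quality threshold.
#'
#' @param rec An [alignment_records()] data frame (any number of rows).
#' @param f A [filter_config()].
#' @return A logical vector, one element per record.
#' @export
passes_filters <- function(rec, f = filter_config()) {
  flag <- as.integer(rec$flag)
  keep <- !has_flag(flag, FLAG_UNMAPPED) & !has_flag(flag, FLAG_QCFAIL)
  if (!f$include_secondary) keep <- keep & !has_flag(flag, FLAG_SECONDARY)
  if (!f$include_supplementary)
    keep <- keep & !has_flag(flag, FLAG_SUPPLEMENTARY)
  if (!f$include_duplicates) keep <- keep & !has_flag(flag, FLAG_DUPLICATE)
  keep & as.integer(rec$mapq) >= f$min_mapping_quality
}

resolve_chromosome <- function(available, wanted, strict = FALSE) {
  hit <- available[chrom_matches(available, wanted, strict)]
  if (length(hit) == 0L)
    stop("chromosome '", wanted, "' not present in alignment file; ",
         "available: ", paste(available, collapse = ", "), call. = FALSE)
  hit[1]
}

#' Read the alignment records overlapping a locus
#'
#' Fetches every record whose aligned reference span overlaps the locus
#' analysis region, in coordinate order. An `N`-skipped stretch is part of
#' the reference span, so a spliced read bridging the whole region is
#' returned even if none of its aligned bases fall inside it. BAM input is
#' queried through its index; SAM input is converted to a sorted, indexed
#' temporary BAM first.
#'
#' @param path A coordinate-sorted BAM (with `.bai` index) or SAM file.
#' @param region A `normalized_locus` from [normalize_locus()], or a list
#'   with fields `chromosome`, `analysis_region` (0-based half-open) and
#'   optionally `strict_chrom`.
#' @return An [alignment_records()] data frame ordered by position.
#' @export
read_alignments <- function(path, region) {
  if (!file.exists(path))
    stop("alignment file not found: ", path, call. = FALSE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    tmp <- tempfile(fileext = ".bam")
    bam <- suppressMessages(
      Rsamtools::asBam(path, sub("\\.bam$", "", tmp),
                       overwrite = TRUE, indexDestination = TRUE))
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  } else {
    bam <- path
    idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
    if (!any(file.exists(idx)))
      stop("no index found for '", path,
           "'; create one with samtools index or Rsamtools::indexBam()",
           call. = FALSE)
  }
  header_seqs <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  chrom <- resolve_chromosome(header_seqs, region$chromosome,
                              isTRUE(region$strict_chrom))
  ar <- region$analysis_region
  which <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(ar[1] + 1L, ar[2]))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    which = which)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos)
  rec <- alignment_records(qname = res$qname[keep],
                           flag = res$flag[keep],
                           rname = as.character(res$rname)[keep],
                           pos = res$pos[keep] - 1L,
                           mapq = res$mapq[keep],
                           cigar = res$cigar[keep])
  # deterministic tie order regardless of upstream sort stability
  rec[order(rec$pos, rec$qname, rec$flag), , drop = FALSE]
}
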