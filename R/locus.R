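#' Describe the target splicing event
#'
#' A locus configuration holds the genomic coordinates of a single two-exon
#' splicing event: exon 1, the intron whose retention is quantified, and
#' exon 2. Coordinates are 1-based inclusive, matching SAM/GFF convention and
#' the way coordinates are printed in genome browsers, so published values can
#' be pasted directly into a config. All internal arithmetic uses 0-based
#' half-open intervals (see [normalize_locus()]).
#'
#' @param locus_name Short identifier for the event (e.g. `"FMR1_intron1"`).
#' @param chromosome Reference sequence name. `"chrX"` and `"X"` dialects are
#'   matched interchangeably unless `strict_chrom = TRUE`.
#' @param exon1,intron1,exon2 Length-2 integer vectors `c(start, end)`,
#'   1-based inclusive. The three intervals must be contiguous:
#'   `exon1[2] + 1 == intron1[1]` and `intron1[2] + 1 == exon2[1]`.
#' @param window_bp Width in bases of the window around each splice site
#'   within which a CIGAR `N` skip boundary is accepted as matching that
#'   site (default 50).
#' @param transcript_region Optional `c(start, end)` of the aberrant
#'   transcript (e.g. the exon1 + pseudo-exon isoform); must overlap exon 1
#'   and the intron. Recorded for track export, not used in counting.
#' @param strand Optional strand (`"+"`, `"-"` or `NA`). Recorded; counting
#'   is strand-agnostic unless `stranded = TRUE`.
#' @param stranded Restrict counting to records on `strand` (default FALSE).
#' @param strict_chrom Disable "chr"-prefix-insensitive chromosome matching.
#'
#' @return An object of class `locus_config`.
#' @seealso [load_locus_config()], [normalize_locus()]
#' @examples
#' fmr1 <- locus_config("FMR1_intron1", "chrX",
#'   exon1  = c(147911619, 147912229),
#'   intron1 = c(147912230, 147921932),
#'   exon2  = c(147921933, 147921985))
#' fmr1
#' @export
locus_config <- function(locus_name, chromosome, exon1, intron1, exon2,
                         window_bp = 50L, transcript_region = NULL,
                         strand = NA_character_, stranded = FALSE,
                         strict_chrom = FALSE) {
  cfg <- structure(
    list(locus_name = as.character(locus_name)[1],
         chromosome = as.character(chromosome)[1],
         exon1 = as_interval(exon1, "exon1"),
         intron1 = as_interval(intron1, "intron1"),
         exon2 = as_interval(exon2, "exon2"),
         window_bp = as.integer(window_bp)[1],
         transcript_region = if (is.null(transcript_region)) NULL
                             else as_interval(transcript_region,
                                              "transcript_region"),
         strand = as.character(strand)[1],
         stranded = isTRUE(stranded),
         strict_chrom = isTRUE(strict_chrom)),
    class = "locus_config")
  validate_locus_config(cfg)
  cfg
}

as_interval <- function(x, what) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 2 || anyNA(x))
    stop("interval '", what, "' must be two numbers c(start, end)",
         call. = FALSE)
  as.integer(round(x))
}

validate_locus_config <- function(cfg) {
  for (f in c("locus_name", "chromosome", "exon1", "intron1", "exon2",
              "window_bp"))
    if (is.null(cfg[[f]]) || (is.character(cfg[[f]]) && !nzchar(cfg[[f]])))
      stop("locus config is missing required field '", f, "'", call. = FALSE)
  for (f in c("exon1", "intron1", "exon2", "transcript_region")) {
    iv <- cfg[[f]]
    if (is.null(iv)) next
    if (iv[1] > iv[2])
      stop("invalid interval for '", f, "': start ", iv[1],
           " exceeds end ", iv[2], call. = FALSE)
    if (iv[1] < 1)
      stop("interval '", f, "' must have start >= 1 (1-based coordinates)",
           call. = FALSE)
  }
  if (cfg$exon1[2] + 1L != cfg$intron1[1])
    stop("contiguity violation: exon1 ends at ", cfg$exon1[2],
         " but intron1 starts at ", cfg$intron1[1],
         " (expected exon1 end + 1 == intron start)", call. = FALSE)
  if (cfg$intron1[2] + 1L != cfg$exon2[1])
    stop("contiguity violation: intron1 ends at ", cfg$intron1[2],
         " but exon2 starts at ", cfg$exon2[1],
         " (expected intron end + 1 == exon2 start)", call. = FALSE)
  if (cfg$window_bp < 1L)
    stop("window_bp must be >= 1", call. = FALSE)
  tr <- cfg$transcript_region
  if (!is.null(tr)) {
    overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
    if (!overlaps(tr, cfg$exon1) || !overlaps(tr, cfg$intron1))
      stop("transcript_region must overlap both exon1 and intron1",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.locus_config <- function(x, ...) {
  fmt <- function(iv) sprintf("%s:%s-%s", x$chromosome,
                              format(iv[1], big.mark = ","),
                              format(iv[2], big.mark = ","))
  cat("Locus configuration '", x$locus_name, "'\n", sep = "")
  cat("  exon1   ", fmt(x$exon1), "\n")
  cat("  intron1 ", fmt(x$intron1),
      sprintf(" (length %s)", format(diff(x$intron1) + 1L, big.mark = ",")),
      "\n", sep = "")
  cat("  exon2   ", fmt(x$exon2), "\n")
  cat("  junction window:", x$window_bp, "bp\n")
  if (!is.null(x$transcript_region))
    cat("  transcript region", fmt(x$transcript_region), "\n")
  invisible(x)
}

#' Load a locus configuration from a key-value text file
#'
#' The file dialect is flat `key = value` (or `key: value` / `key<TAB>value`)
#' lines; `#` starts a comment. Recognised keys: `locus_name`, `chromosome`,
#' `exon1`, `intron1`, `exon2`, `window_bp`, `transcript_region`, `strand`,
#' `stranded`, `strict_chrom`. Intervals are written `start-end`; thousands
#' separators (commas) inside numbers are ignored, so browser-style
#' coordinates such as `147,912,230-147,921,932` parse as-is.
#'
#' @param path Path to the config file.
#' @return A validated [locus_config()] object.
#' @export
load_locus_config <- function(path) {
  if (!file.exists(path))
    stop("locus config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:\t ]\\s*(.+)$",
                                  lines))
  bad <- lengths(kv) != 3
  if (any(bad))
    stop("unparseable locus config line: '", lines[bad][1], "'", call. = FALSE)
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  names(vals) <- keys
  known <- c("locus_name", "chromosome", "exon1", "intron1", "exon2",
             "window_bp", "transcript_region", "strand", "stranded",
             "strict_chrom")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    warning("ignoring unknown locus config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  need <- c("locus_name", "chromosome", "exon1", "intron1", "exon2")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("locus config is missing required field '", missing[1], "'",
         call. = FALSE)
  locus_config(
    locus_name = vals[["locus_name"]],
    chromosome = vals[["chromosome"]],
    exon1 = parse_interval(vals[["exon1"]], "exon1"),
    intron1 = parse_interval(vals[["intron1"]], "intron1"),
    exon2 = parse_interval(vals[["exon2"]], "exon2"),
    window_bp = if ("window_bp" %in% keys)
      as.integer(gsub(",", "", vals[["window_bp"]])) else 50L,
    transcript_region = if ("transcript_region" %in% keys)
      parse_interval(vals[["transcript_region"]], "transcript_region")
      else NULL,
    strand = if ("strand" %in% keys) vals[["strand"]] else NA_character_,
    stranded = "stranded" %in% keys &&
      tolower(vals[["stranded"]]) %in% c("true", "yes", "1"),
    strict_chrom = "strict_chrom" %in% keys &&
      tolower(vals[["strict_chrom"]]) %in% c("true", "yes", "1"))
}

parse_interval <- function(text, what) {
  text <- gsub(",", "", text)
  m <- regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", trimws(text))
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 3)
    stop("interval '", what, "' must be written start-end, got '", text, "'",
         call. = FALSE)
  as.integer(as.numeric(parts[2:3]))
}

#' Write a locus configuration to its key-value text form
#'
#' @param cfg A [locus_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "locus_config"))
  iv <- function(x) sprintf("%d-%d", x[1], x[2])
  lines <- c(
    paste("locus_name =", cfg$locus_name),
    paste("chromosome =", cfg$chromosome),
    paste("exon1 =", iv(cfg$exon1)),
    paste("intron1 =", iv(cfg$intron1)),
    paste("exon2 =", iv(cfg$exon2)),
    paste("window_bp =", cfg$window_bp))
  if (!is.null(cfg$transcript_region))
    lines <- c(lines, paste("transcript_region =", iv(cfg$transcript_region)))
  if (!is.na(cfg$strand)) lines <- c(lines, paste("strand =", cfg$strand))
  if (cfg$stranded) lines <- c(lines, "stranded = true")
  if (cfg$strict_chrom) lines <- c(lines, "strict_chrom = true")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a locus configuration to internal 0-based coordinates
#'
#' Converts the 1-based inclusive intervals of a [locus_config()] to the
#' 0-based half-open representation used by all counting arithmetic. The
#' donor site is the 0-based coordinate of the first intronic base; the
#' acceptor site is one past the last intronic base, so
#' `acceptor - donor` equals the intron length and a canonical spliced
#' alignment skips exactly `[donor, acceptor)`.
#'
#' @param cfg A validated [locus_config()].
#' @return An object of class `normalized_locus` with fields `chromosome`,
#'   `exon1`, `intron`, `exon2` (0-based half-open `c(start, end)`),
#'   `donor_site`, `acceptor_site`, `window_bp` and `analysis_region`
#'   (exon1 through exon2 padded by `window_bp` on each side).
#' @export
normalize_locus <- function(cfg) {
  validate_locus_config(cfg)
  half_open <- function(iv) c(iv[1] - 1L, iv[2])
  intron <- half_open(cfg$intron1)
  exon1 <- half_open(cfg$exon1)
  exon2 <- half_open(cfg$exon2)
  structure(
    list(locus_name = cfg$locus_name,
         chromosome = cfg$chromosome,
         exon1 = exon1,
         intron = intron,
         exon2 = exon2,
         donor_site = intron[1],
         acceptor_site = intron[2],
         window_bp = cfg$window_bp,
         analysis_region = c(max(0L, exon1[1] - cfg$window_bp),
                             exon2[2] + cfg$window_bp),
         transcript_region = if (is.null(cfg$transcript_region)) NULL
                             else half_open(cfg$transcript_region),
         strand = cfg$strand,
         stranded = cfg$stranded,
         strict_chrom = cfg$strict_chrom),
    class = "normalized_locus")
}

#' Recover the 1-based locus configuration from its normalized form
#'
#' Inverse of [normalize_locus()]; used to verify that coordinate conversion
#' is lossless.
#'
#' @param nl A `normalized_locus`.
#' @return A [locus_config()] object equal to the one normalized.
#' @export
denormalize_locus <- function(nl) {
  stopifnot(inherits(nl, "normalized_locus"))
  closed <- function(iv) c(iv[1] + 1L, iv[2])
  locus_config(
    locus_name = nl$locus_name,
    chromosome = nl$chromosome,
    exon1 = closed(nl$exon1),
    intron1 = closed(nl$intron),
    exon2 = closed(nl$exon2),
    window_bp = nl$window_bp,
    transcript_region = if (is.null(nl$transcript_region)) NULL
                        else closed(nl$transcript_region),
    strand = nl$strand,
    stranded = nl$stranded,
    strict_chrom = nl$strict_chrom)
}

#' @export
print.normalized_locus <- function(x, ...) {
  cat("Normalized locus '", x$locus_name, "' on ", x$chromosome,
      " (0-based half-open)\n", sep = "")
  cat("  intron [", x$intron[1], ", ", x$intron[2], ")  donor ", x$donor_site,
      "  acceptor ", x$acceptor_site, "\n", sep = "")
  cat("  analysis region [", x$analysis_region[1], ", ",
      x$analysis_region[2], ")\n", sep = "")
  invisible(x)
}

# chromosome dialect matching: "chrX" and "X" refer to the same sequence
# unless strict mode is on
chrom_matches <- function(a, b, strict = FALSE) {
  if (strict) return(a == b)
  sub("^chr", "", a) == sub("^chr", "", b)
}
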