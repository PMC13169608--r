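#' Define a toy two-exon locus for simulation
#'
#' A compact exon1-intron-exon2 gene model with a pseudo-exon inside the
#' intron, mimicking the geometry of a mis-splicing event in which a
#' cryptic acceptor inside intron 1 creates a two-exon aberrant isoform.
#' Positions are expressed as lengths and donor offsets so the model is
#' trivially relocatable.
#'
#' @param chromosome Reference name (default `"chrT"`).
#' @param exon1_len,intron_len,exon2_len Segment lengths in bases
#'   (defaults 500, 2000, 500).
#' @param pseudo_exon Half-open offsets of the pseudo-exon from the donor
#'   site, default `c(100, 400)`. For simulated truth labels to coincide
#'   with windowed classification, the start offset must exceed the
#'   junction window width.
#' @param origin 1-based genomic start coordinate of exon 1 (default 101,
#'   leaving a 100 bp flank).
#' @param flank Reference bases beyond exon 2 (default 100).
#' @return An object of class `toy_locus`.
#' @export
toy_locus <- function(chromosome = "chrT", exon1_len = 500L,
                      intron_len = 2000L, exon2_len = 500L,
                      pseudo_exon = c(100L, 400L), origin = 101L,
                      flank = 100L) {
  t <- structure(list(chromosome = as.character(chromosome),
                      exon1_len = as.integer(exon1_len),
                      intron_len = as.integer(intron_len),
                      exon2_len = as.integer(exon2_len),
                      pseudo_exon = as.integer(pseudo_exon),
                      origin = as.integer(origin),
                      flank = as.integer(flank)),
                 class = "toy_locus")
  with(t, {
    stopifnot(exon1_len > 0L, intron_len > 0L, exon2_len > 0L,
              origin >= 1L, flank >= 0L)
    if (length(pseudo_exon) != 2L || pseudo_exon[1] >= pseudo_exon[2] ||
        pseudo_exon[1] < 0L || pseudo_exon[2] > intron_len)
      stop("pseudo_exon offsets must satisfy 0 <= start < end <= intron_len",
           call. = FALSE)
  })
  t
}

#' Locus configuration implied by a toy locus
#'
#' @param t A [toy_locus()].
#' @param window_bp Junction window width for the config (default 50).
#' @return A [locus_config()] whose intervals are contiguous by
#'   construction; the transcript region spans exon 1 through the end of
#'   the pseudo-exon, the extent of the aberrant isoform.
#' @export
toy_locus_config <- function(t, window_bp = 50L) {
  stopifnot(inherits(t, "toy_locus"))
  o <- t$origin
  e1_end <- o + t$exon1_len - 1L
  in_end <- e1_end + t$intron_len
  locus_config(
    locus_name = "toy_locus", chromosome = t$chromosome,
    exon1 = c(o, e1_end),
    intron1 = c(e1_end + 1L, in_end),
    exon2 = c(in_end + 1L, in_end + t$exon2_len),
    window_bp = window_bp,
    transcript_region = c(o, e1_end + t$pseudo_exon[2]))
}

#' Build the reference sequence and configuration of a toy locus
#'
#' The reference is a seeded pseudo-random nucleotide sequence spanning
#' coordinate 1 through the end of the downstream flank, so simulated
#' alignments can be written as a complete, index-able SAM/FASTA pair.
#'
#' @param t A [toy_locus()].
#' @param seed Seed for the reference sequence (default 1).
#' @param window_bp Junction window for the generated config.
#' @return A list with `reference` (single character string) and `config`
#'   (a [locus_config()]).
#' @export
build_toy_locus <- function(t, seed = 1L, window_bp = 50L) {
  stopifnot(inherits(t, "toy_locus"))
  len <- t$origin - 1L + t$exon1_len + t$intron_len + t$exon2_len + t$flank
  restore <- local_seed(seed)
  on.exit(restore())
  reference <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
  list(reference = reference, config = toy_locus_config(t, window_bp))
}

#' Parameters of the read simulation
#'
#' @param mis_fraction Fraction `f` of transcripts that are the aberrant
#'   exon1-pseudo-exon isoform.
#' @param retained_fraction Fraction `r` of fully intron-retained
#'   pre-mRNA; the remaining `1 - f - r` is canonically spliced.
#' @param read_len Read length in bases (default 150).
#' @param n_reads Number of fragments to simulate (default 20000; each
#'   fragment yields two records when `paired`).
#' @param paired Paired-end sequencing (default TRUE).
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution:
#'   lengths are drawn from the normal density discretized and truncated
#'   to `[read_len, transcript length]` (defaults 300, 50).
#' @param seed Seed driving all randomness of the simulation (default 1).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(mis_fraction = 0, retained_fraction = 0,
                              read_len = 150L, n_reads = 20000L,
                              paired = TRUE, fragment_len_mean = 300,
                              fragment_len_sd = 50, seed = 1L) {
  p <- structure(list(mis_fraction = as.numeric(mis_fraction),
                      retained_fraction = as.numeric(retained_fraction),
                      read_len = as.integer(read_len),
                      n_reads = as.integer(n_reads),
                      paired = isTRUE(paired),
                      fragment_len_mean = as.numeric(fragment_len_mean),
                      fragment_len_sd = as.numeric(fragment_len_sd),
                      seed = as.integer(seed)),
                 class = "simulation_params")
  if (p$mis_fraction < 0 || p$retained_fraction < 0 ||
      p$mis_fraction + p$retained_fraction > 1 + 1e-12)
    stop("isoform fractions must be non-negative with f + r <= 1",
         call. = FALSE)
  if (p$read_len < 1L || p$n_reads < 0L)
    stop("read_len must be positive and n_reads non-negative",
         call. = FALSE)
  if (p$fragment_len_mean <= 0 || p$fragment_len_sd <= 0)
    stop("fragment length mean and sd must be positive", call. = FALSE)
  p
}

ISOFORMS <- c("canonical", "mis_spliced", "retained")

# per-isoform mature transcript structure: list(len, block1_len, gap)
# 2-block isoforms are (block1, N gap, block2); retained is a single block
isoform_geometry <- function(t) {
  pe <- t$pseudo_exon
  list(
    canonical = list(len = t$exon1_len + t$exon2_len,
                     block1 = t$exon1_len, gap = t$intron_len),
    mis_spliced = list(len = t$exon1_len + (pe[2] - pe[1]),
                       block1 = t$exon1_len, gap = pe[1]),
    retained = list(len = t$exon1_len + t$intron_len + t$exon2_len,
                    block1 = NA_integer_, gap = NA_integer_))
}

# project transcript start positions to genomic (pos0, cigar); vectorized
# over s for one isoform
project_reads <- function(iso, s, t, read_len) {
  g0 <- t$origin - 1L                    # 0-based genomic exon1 start
  geo <- isoform_geometry(t)[[iso]]
  rl <- read_len
  if (iso == "retained") {
    return(list(pos = g0 + s, cigar = sprintf("%dM", rl)))
  }
  b1 <- geo$block1; gap <- geo$gap
  pos <- integer(length(s))
  cigar <- character(length(s))
  left <- s + rl <= b1
  right <- s >= b1
  span <- !left & !right
  pos[left] <- g0 + s[left]
  cigar[left] <- sprintf("%dM", rl)
  pos[right] <- g0 + b1 + gap + (s[right] - b1)
  cigar[right] <- sprintf("%dM", rl)
  m1 <- b1 - s[span]
  pos[span] <- g0 + s[span]
  cigar[span] <- sprintf("%dM%dN%dM", m1, gap, rl - m1)
  list(pos = pos, cigar = cigar)
}

# geometric ground-truth category, independent of the classifier: a
# junction-crossing canonical read is canonical_junction, a
# junction-crossing aberrant read is cryptic_junction, reads whose aligned
# bases sit wholly inside the intron (pseudo-exon included) are
# intron_contained, anything else unclassified. Valid when the pseudo-exon
# donor offset exceeds the junction window.
truth_category <- function(iso, s, t, read_len) {
  e1 <- t$exon1_len; il <- t$intron_len
  crosses <- s < e1 & s + read_len > e1
  out <- rep("unclassified", length(s))
  if (iso == "canonical") {
    out[crosses] <- "canonical_junction"
  } else if (iso == "mis_spliced") {
    out[crosses] <- "cryptic_junction"
    out[s >= e1] <- "intron_contained"
  } else {
    out[s >= e1 & s + read_len <= e1 + il] <- "intron_contained"
  }
  out
}

# discrete truncated-normal fragment length distribution on
# [read_len, transcript_len]
fragment_len_weights <- function(p, tlen) {
  support <- p$read_len:tlen
  w <- stats::dnorm(support, p$fragment_len_mean, p$fragment_len_sd)
  if (sum(w) <= 0) w <- rep(1, length(support))
  list(support = support, prob = w / sum(w))
}

#' Simulate spliced reads from a known isoform mixture
#'
#' Error-free reads are drawn from three transcript sources — canonical
#' (exon1-exon2 junction, CIGAR `N` spanning the intron), mis-spliced
#' (exon1 joined to the intronic pseudo-exon, `N` spanning the donor
#' offset) and fully intron-retained pre-mRNA (pure `M`) — with uniform
#' start positions on the chosen mature transcript. All randomness flows
#' from `p$seed`; the stream order is isoform draws, then per isoform
#' (canonical, mis-spliced, retained) fragment lengths followed by start
#' positions, so output is reproducible across runs.
#'
#' @param t A [toy_locus()].
#' @param p A [simulation_params()].
#' @return A list with `records` (an [alignment_records()] data frame,
#'   coordinate-sorted, with mate columns for SAM output), `truth` (one
#'   row per record: `qname`, `mate`, `isoform`, `tstart`,
#'   `expected_category`) and `rates` (the [expected_psi()] oracle).
#' @export
simulate_reads <- function(t, p) {
  stopifnot(inherits(t, "toy_locus"), inherits(p, "simulation_params"))
  geo <- isoform_geometry(t)
  rl <- p$read_len
  min_len <- min(vapply(geo, `[[`, numeric(1), "len"))
  if (rl > min_len)
    stop("read_len ", rl, " exceeds the shortest transcript (", min_len,
         " bases)", call. = FALSE)
  restore <- local_seed(p$seed)
  on.exit(restore())
  n <- p$n_reads
  mix <- c(1 - p$mis_fraction - p$retained_fraction, p$mis_fraction,
           p$retained_fraction)
  iso_idx <- if (n) sample.int(3L, n, replace = TRUE, prob = mix)
             else integer(0)
  frag <- vector("list", 3L)
  for (k in 1:3) {
    n_k <- sum(iso_idx == k)
    if (n_k == 0L) { frag[[k]] <- NULL; next }
    iso <- ISOFORMS[k]
    tlen <- geo[[iso]]$len
    if (p$paired) {
      fl <- fragment_len_weights(p, tlen)
      F <- fl$support[sample.int(length(fl$support), n_k, replace = TRUE,
                                 prob = fl$prob)]
      fs <- as.integer(floor(stats::runif(n_k) * (tlen - F + 1)))
      starts <- cbind(fs, fs + F - rl)
    } else {
      starts <- cbind(as.integer(floor(stats::runif(n_k) *
                                       (tlen - rl + 1))))
    }
    frag[[k]] <- starts
  }
  n_mates <- if (p$paired) 2L else 1L
  qname <- sprintf("sim%07d", seq_len(n))
  rec_list <- vector("list", 3L)
  truth_list <- vector("list", 3L)
  for (k in 1:3) {
    idx <- which(iso_idx == k)
    if (!length(idx)) next
    iso <- ISOFORMS[k]
    starts <- frag[[k]]
    per_mate <- vector("list", n_mates)
    for (m in seq_len(n_mates)) {
      pr <- project_reads(iso, starts[, m], t, rl)
      span <- GenomicAlignments::cigarWidthAlongReferenceSpace(pr$cigar)
      per_mate[[m]] <- data.frame(qname = qname[idx], pos = pr$pos,
                                  cigar = pr$cigar, span = span,
                                  tstart = starts[, m], mate = m,
                                  stringsAsFactors = FALSE)
    }
    if (p$paired) {
      m1 <- per_mate[[1]]; m2 <- per_mate[[2]]
      tlen_out <- (m2$pos + m2$span) - m1$pos
      m1$flag <- 99L;  m1$pnext <- m2$pos + 1L; m1$tlen <- tlen_out
      m2$flag <- 147L; m2$pnext <- m1$pos + 1L; m2$tlen <- -tlen_out
      df <- rbind(m1, m2)
    } else {
      df <- per_mate[[1]]
      df$flag <- 0L; df$pnext <- 0L; df$tlen <- 0L
    }
    df$isoform <- iso
    df$expected_category <- truth_category(iso, df$tstart, t, rl)
    rec_list[[k]] <- df
  }
  all <- do.call(rbind, rec_list)
  if (is.null(all))
    all <- data.frame(qname = character(), pos = integer(),
                      cigar = character(), span = integer(),
                      tstart = integer(), mate = integer(),
                      flag = integer(), pnext = integer(), tlen = integer(),
                      isoform = character(),
                      expected_category = character(),
                      stringsAsFactors = FALSE)
  ord <- order(all$pos, all$qname, all$mate)
  all <- all[ord, , drop = FALSE]
  records <- alignment_records(
    qname = all$qname, flag = all$flag, rname = t$chromosome,
    pos = all$pos, mapq = 255L, cigar = all$cigar,
    rnext = if (p$paired) "=" else "*", pnext = all$pnext,
    tlen = all$tlen)
  truth <- data.frame(qname = all$qname, mate = all$mate,
                      isoform = all$isoform, tstart = all$tstart,
                      expected_category = all$expected_category,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, rates = expected_psi(t, p))
}

#' Analytic expected PSI of a simulation setting
#'
#' Computes the exact per-read category probabilities implied by a toy
#' locus and simulation parameters by exhaustive enumeration: every
#' (isoform, transcript start) template read is built, classified with the
#' production classifier, and the indicators are averaged over the uniform
#' start distribution (for paired reads, over the exact discrete fragment
#' length mixture used by the simulator) and weighted by the isoform
#' mixture. The expected PSI follows from the PSI formula applied to the
#' canonical-junction and intron-contained rates.
#'
#' @param t A [toy_locus()].
#' @param p A [simulation_params()].
#' @param ccfg A [classifier_config()] (defaults match the pipeline
#'   defaults).
#' @param window_bp Junction window of the implied locus config.
#' @return An object of class `simulation_truth`: a list with
#'   `expected_psi`, `expected_junction_rate`, `expected_intron_rate`,
#'   `expected_cryptic_rate`, `expected_unclassified_rate` and the
#'   `per_isoform` rate matrix.
#' @export
expected_psi <- function(t, p, ccfg = classifier_config(),
                         window_bp = 50L) {
  stopifnot(inherits(t, "toy_locus"), inherits(p, "simulation_params"))
  geo <- isoform_geometry(t)
  rl <- p$read_len
  nl <- normalize_locus(toy_locus_config(t, window_bp))
  mix <- c(1 - p$mis_fraction - p$retained_fraction, p$mis_fraction,
           p$retained_fraction)
  names(mix) <- ISOFORMS
  per_iso <- matrix(0, nrow = 3, ncol = 4,
                    dimnames = list(ISOFORMS, READ_CATEGORIES))
  for (iso in ISOFORMS) {
    tlen <- geo[[iso]]$len
    if (rl > tlen)
      stop("read_len exceeds transcript '", iso, "'", call. = FALSE)
    s <- 0:(tlen - rl)
    pr <- project_reads(iso, s, t, rl)
    tmpl <- alignment_records(qname = sprintf("t%d", s), flag = 0L,
                              rname = t$chromosome, pos = pr$pos,
                              mapq = 255L, cigar = pr$cigar)
    cats <- classify_records(tmpl, nl, ccfg)
    ind <- vapply(READ_CATEGORIES, function(cat) as.numeric(cats == cat),
                  numeric(length(s)))
    ind <- matrix(ind, ncol = length(READ_CATEGORIES))
    if (!p$paired) {
      per_iso[iso, ] <- colMeans(ind)
    } else {
      fl <- fragment_len_weights(p, tlen)
      cum <- apply(ind, 2, cumsum)          # cum[i, ] = sum over s < i
      cum <- rbind(0, cum)
      total <- cum[nrow(cum), ]
      acc <- numeric(4)
      for (fi in seq_along(fl$support)) {
        F <- fl$support[fi]
        nF <- tlen - F + 1
        # mate1 starts are 0..tlen-F; mate2 starts are F-rl..tlen-rl
        mate1 <- cum[tlen - F + 2, ]
        mate2 <- total - cum[F - rl + 1, ]
        acc <- acc + fl$prob[fi] * (mate1 + mate2) / (2 * nF)
      }
      per_iso[iso, ] <- acc
    }
  }
  rates <- as.numeric(mix %*% per_iso)
  names(rates) <- READ_CATEGORIES
  j <- rates[["canonical_junction"]]
  i <- rates[["intron_contained"]]
  structure(list(
    expected_psi = if (j + i > 0) i / (j + i) else NA_real_,
    expected_junction_rate = j,
    expected_intron_rate = i,
    expected_cryptic_rate = rates[["cryptic_junction"]],
    expected_unclassified_rate = rates[["unclassified"]],
    per_isoform = per_iso,
    mixture = mix), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation truth rates (per read):\n")
  cat(sprintf("  junction %.4f  intron %.4f  cryptic %.4f  expected PSI %s\n",
              x$expected_junction_rate, x$expected_intron_rate,
              x$expected_cryptic_rate,
              ifelse(is.na(x$expected_psi), "NA",
                     sprintf("%.4f", x$expected_psi))))
  invisible(x)
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' Produces a header-complete SAM (HD, SQ, PG lines) convertible to an
#' indexed BAM. Read sequences are reconstructed from the reference over
#' the `M` blocks when a reference is supplied (simulated reads are
#' error-free), otherwise written as `*`.
#'
#' @param records An [alignment_records()] data frame sorted by position;
#'   optional columns `rnext`, `pnext`, `tlen` are honoured.
#' @param reference Reference sequence string (coordinate 1 onward), or
#'   `NULL`.
#' @param path Output SAM path.
#' @param chromosome Reference name for the `@SQ` line (taken from the
#'   records if omitted).
#' @param reference_length `@SQ` length; defaults to `nchar(reference)` or
#'   the maximal aligned end.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reference = NULL, path,
                      chromosome = NULL, reference_length = NULL) {
  rec <- as.data.frame(records)
  if (nrow(rec) && is.unsorted(rec$pos))
    stop("records must be sorted by position before writing", call. = FALSE)
  if (is.null(chromosome))
    chromosome <- if (nrow(rec)) rec$rname[1] else "chrUn"
  span <- if (nrow(rec))
    rec$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  else integer(0)
  if (is.null(reference_length))
    reference_length <- if (!is.null(reference)) nchar(reference)
                        else max(c(span, 1L))
  if (nrow(rec) && any(span > reference_length))
    stop("alignment extends past the reference end", call. = FALSE)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chromosome,
                      as.integer(reference_length)),
              sprintf("@PG\tID:splicewatch\tPN:splicewatch\tVN:%s",
                      as.character(utils::packageVersion("splicewatch"))))
  if (nrow(rec) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  seq <- rep("*", nrow(rec))
  qual <- rep("*", nrow(rec))
  if (!is.null(reference)) {
    mb <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      rec$cigar, pos = rec$pos + 1L, ops = c("M", "=", "X"),
      drop.empty.ranges = TRUE)
    nb <- S4Vectors::elementNROWS(mb)
    flat <- BiocGenerics::unlist(mb, use.names = FALSE)
    pieces <- substring(reference, IRanges::start(flat),
                        IRanges::end(flat))
    seq <- vapply(split(pieces, rep(seq_len(nrow(rec)), nb)),
                  paste0, "", collapse = "")
    seq <- seq[order(as.integer(names(seq)))]
    qual <- vapply(nchar(seq), function(w) strrep("I", w), "")
  }
  rnext <- if ("rnext" %in% names(rec)) rec$rnext else "*"
  pnext <- if ("pnext" %in% names(rec)) rec$pnext else 0L
  tlen <- if ("tlen" %in% names(rec)) rec$tlen else 0L
  body <- paste(rec$qname, rec$flag, chromosome, rec$pos + 1L, rec$mapq,
                rec$cigar, rnext, pnext, tlen, seq, qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a reference sequence as FASTA
#' @param reference Reference sequence string.
#' @param chromosome Sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, chromosome, path) {
  dna <- Biostrings::DNAStringSet(reference)
  names(dna) <- chromosome
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write simulation truth labels as TSV
#' @param truth The `truth` data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# run code under a seed, restoring the caller's RNG state afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
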