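#' Quantify mis-splicing across samples
#'
#' End-to-end quantification: for each alignment file, fetch the records
#' overlapping the locus, classify and count them, compute PSI / splicing
#' efficiency, and export coverage (bedGraph) and junction tables. A run
#' manifest recording the tool version, config digest, input digests and
#' settings is written alongside the outputs.
#'
#' @param locus A [locus_config()] object or the path of a locus config
#'   file.
#' @param alignment_paths Character vector of BAM (indexed) or SAM files.
#' @param sample_ids One label per file (defaults to file base names).
#' @param out_dir Output directory, created if needed.
#' @param fcfg A [filter_config()].
#' @param ccfg A [classifier_config()].
#' @param scale_pairs Optional list of `c(id_a, id_b)` sample pairs whose
#'   coverage tracks are additionally written rescaled to the pair-wide
#'   maximum depth (the browser-figure convention).
#' @return Invisibly, a list with `counts`, `metrics`, `junctions` and the
#'   per-sample `tracks`.
#' @export
run_quantify <- function(locus, alignment_paths, sample_ids = NULL,
                         out_dir = ".", fcfg = filter_config(),
                         ccfg = classifier_config(), scale_pairs = NULL) {
  cfg <- if (inherits(locus, "locus_config")) locus
         else load_locus_config(locus)
  nl <- normalize_locus(cfg)
  if (is.null(sample_ids))
    sample_ids <- sub("\\.(bam|sam)$", "", basename(alignment_paths),
                      ignore.case = TRUE)
  if (length(sample_ids) != length(alignment_paths))
    stop("need exactly one sample_id per alignment file", call. = FALSE)
  missing <- alignment_paths[!file.exists(alignment_paths)]
  if (length(missing))
    stop("alignment file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- list(); metrics <- list(); junctions <- list(); tracks <- list()
  for (i in seq_along(alignment_paths)) {
    sid <- sample_ids[i]
    rec <- read_alignments(alignment_paths[i], nl)
    counts[[sid]] <- count_reads(rec, nl, fcfg, ccfg, sample_id = sid)
    metrics[[sid]] <- compute_metrics(counts[[sid]])
    tracks[[sid]] <- compute_coverage(rec, nl$analysis_region, fcfg,
                                      sample_id = sid,
                                      chromosome = nl$chromosome)
    junctions[[sid]] <- junction_counts(rec, nl, fcfg, ccfg,
                                        sample_id = sid)
    write_bedgraph(tracks[[sid]],
                   file.path(out_dir, paste0(sid, ".bedGraph")))
    write_junctions_tsv(junctions[[sid]],
                        file.path(out_dir, paste0(sid, ".junctions.tsv")),
                        file.path(out_dir, paste0(sid, ".junctions.bed")))
  }
  counts_df <- do.call(rbind, counts)
  metrics_df <- do.call(rbind, metrics)
  rownames(counts_df) <- rownames(metrics_df) <- NULL
  write_counts_tsv(counts_df, file.path(out_dir, "counts.tsv"))
  write_metrics_tsv(metrics_df, file.path(out_dir, "metrics.tsv"))

  if (!is.null(scale_pairs)) {
    for (pair in scale_pairs) {
      sp <- scale_pair(tracks[[pair[1]]], tracks[[pair[2]]])
      if (!sp$degenerate) {
        write_bedgraph(sp$a, file.path(out_dir,
                                       paste0(pair[1], ".scaled.bedGraph")))
        write_bedgraph(sp$b, file.path(out_dir,
                                       paste0(pair[2], ".scaled.bedGraph")))
      }
    }
  }
  write_manifest(out_dir, list(
    command = "quantify",
    locus = unclass_config_digest(cfg),
    inputs = input_digests(alignment_paths, sample_ids),
    filter = unclass(fcfg),
    classifier = unclass(ccfg)))
  invisible(list(counts = counts_df, metrics = metrics_df,
                 junctions = junctions, tracks = tracks))
}

#' Compare groups of counted samples
#'
#' Pools the per-sample informative counts within each group, runs all
#' pairwise two-sided Fisher exact tests, and writes a comparisons TSV
#' with significance stars (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#'
#' @param counts A `read_class_counts` data frame covering all samples
#'   (e.g. the `counts` element returned by [run_quantify()], or read back
#'   from its `counts.tsv`).
#' @param groups Named character vector mapping `sample_id -> group_id`.
#' @param out_dir Output directory.
#' @param adjust Multiple-testing adjustment (see [compare_groups()]).
#' @return Invisibly, the `comparison_results` data frame.
#' @export
run_compare <- function(counts, groups, out_dir = ".",
                        adjust = c("none", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  counts <- as.data.frame(counts)
  unknown <- setdiff(counts$sample_id, names(groups))
  if (length(unknown))
    stop("no group assigned to sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  gid <- groups[counts$sample_id]
  if (length(unique(gid)) < 2L)
    stop("need at least two groups to compare", call. = FALSE)
  pooled <- lapply(split(counts, gid), function(df)
    list(canonical_junction = sum(df$canonical_junction),
         intron_contained = sum(df$intron_contained)))
  res <- compare_groups(pooled, adjust = adjust)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_comparisons_tsv(res, file.path(out_dir, "comparisons.tsv"))
  invisible(res)
}

#' Simulate a sample and write its files
#'
#' Writes the simulated alignments (`reads.sam`, optionally converted to
#' an indexed BAM), the per-read truth table, the reference FASTA, the
#' implied locus config and a manifest into `out_dir`. Deterministic per
#' seed.
#'
#' @param t A [toy_locus()].
#' @param p A [simulation_params()].
#' @param out_dir Output directory.
#' @param bam Also produce `reads.bam` + index (default FALSE).
#' @return Invisibly, the [simulate_reads()] result with `paths` added.
#' @export
run_simulate <- function(t = toy_locus(), p = simulation_params(),
                         out_dir = ".", bam = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  built <- build_toy_locus(t, seed = p$seed)
  sim <- simulate_reads(t, p)
  paths <- list(sam = file.path(out_dir, "reads.sam"),
                truth = file.path(out_dir, "truth.tsv"),
                reference = file.path(out_dir, "reference.fa"),
                locus_config = file.path(out_dir, "locus.config"))
  write_sam(sim$records, built$reference, paths$sam,
            chromosome = t$chromosome)
  write_truth_tsv(sim$truth, paths$truth)
  write_reference_fasta(built$reference, t$chromosome, paths$reference)
  write_locus_config(built$config, paths$locus_config)
  if (bam) {
    paths$bam <- suppressMessages(
      Rsamtools::asBam(paths$sam, file.path(out_dir, "reads"),
                       overwrite = TRUE, indexDestination = TRUE))
  }
  write_manifest(out_dir, list(
    command = "simulate",
    params = unclass(p),
    locus_geometry = unclass(t),
    expected_psi = sim$rates$expected_psi,
    inputs = list()))
  sim$paths <- paths
  invisible(sim)
}

#' Load simulation settings from a key-value text file
#'
#' Dialect as in [load_locus_config()]. Recognised keys:
#' `mis_fraction`, `retained_fraction`, `read_len`, `n_reads`, `paired`,
#' `fragment_len_mean`, `fragment_len_sd`, `seed`, and the toy-locus
#' geometry keys `chromosome`, `exon1_len`, `intron_len`, `exon2_len`,
#' `pseudo_exon` (as `start-end` donor offsets), `origin`, `flank`.
#' Unset keys take the documented defaults.
#'
#' @param path Config file path.
#' @return A list with `locus` (a [toy_locus()]) and `params`
#'   (a [simulation_params()]).
#' @export
load_sim_config <- function(path) {
  if (!file.exists(path))
    stop("simulation config not found: ", path, call. = FALSE)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:\t ]\\s*(.+)$",
                                  lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  names(vals) <- keys
  num <- function(key, default) if (key %in% keys)
    as.numeric(gsub(",", "", vals[[key]])) else default
  flag <- function(key, default) if (key %in% keys)
    tolower(vals[[key]]) %in% c("true", "yes", "1") else default
  locus <- toy_locus(
    chromosome = if ("chromosome" %in% keys) vals[["chromosome"]] else "chrT",
    exon1_len = num("exon1_len", 500L),
    intron_len = num("intron_len", 2000L),
    exon2_len = num("exon2_len", 500L),
    pseudo_exon = if ("pseudo_exon" %in% keys)
      parse_interval(vals[["pseudo_exon"]], "pseudo_exon")
      else c(100L, 400L),
    origin = num("origin", 101L),
    flank = num("flank", 100L))
  params <- simulation_params(
    mis_fraction = num("mis_fraction", 0),
    retained_fraction = num("retained_fraction", 0),
    read_len = num("read_len", 150L),
    n_reads = num("n_reads", 20000L),
    paired = flag("paired", TRUE),
    fragment_len_mean = num("fragment_len_mean", 300),
    fragment_len_sd = num("fragment_len_sd", 50),
    seed = num("seed", 1L))
  list(locus = locus, params = params)
}

unclass_config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_locus_config(cfg, tmp)
  list(locus_name = cfg$locus_name,
       digest = unname(tools::md5sum(tmp)))
}

input_digests <- function(paths, ids) {
  lapply(seq_along(paths), function(i)
    list(sample_id = ids[i], path = basename(paths[i]),
         md5 = unname(tools::md5sum(paths[i]))))
}

write_manifest <- function(out_dir, entries) {
  entries$tool <- "splicewatch"
  entries$version <- as.character(utils::packageVersion("splicewatch"))
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(out_dir, "manifest.json"))
}
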