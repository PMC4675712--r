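#' Assemble a full pipeline configuration
#'
#' Bundles input paths, the scoring scheme, the search configuration and
#' the peak-calling parameters, with every default exactly as in the
#' underlying module functions (bit threshold 30, E-value cap 200,000,
#' 10,000 hits per query, SEG on, cutoff 70).  Either a protein database
#' (internal engine) or a precomputed tabular hits file must be given.
#'
#' @param genome Genome FASTA path.
#' @param annotation GFF3 annotation path.
#' @param protein_db Protein FASTA path (internal search engine), or
#'   `NULL` when `hits_file` is used.
#' @param hits_file 12-column tabular hits from an external engine, or
#'   `NULL`.
#' @param out_dir Output directory.
#' @param cutoff,merge_gap,min_length,strict Peak-calling parameters, see
#'   [call_peaks()].
#' @param quantile Calibration quantile, see [calibrate_cutoff()].
#' @param seed Integer seed for the control stage.
#' @param include_termini Passed to [extract_inter_exon_regions()].
#' @param distinct_clusters Passed to [accumulate_profile()].
#' @param scheme A [scoring_scheme()].
#' @param search A [search_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, protein_db = NULL,
                            hits_file = NULL, out_dir,
                            cutoff = 70L, merge_gap = 0L, min_length = 1L,
                            strict = FALSE, quantile = 1.0, seed = 1L,
                            include_termini = FALSE,
                            distinct_clusters = TRUE,
                            scheme = scoring_scheme(),
                            search = search_config()) {
  if (is.null(protein_db) && is.null(hits_file))
    stop("usage: either a protein database or a hits file is required")
  structure(list(genome = genome, annotation = annotation,
                 protein_db = protein_db, hits_file = hits_file,
                 out_dir = out_dir, cutoff = as.integer(cutoff),
                 merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length),
                 strict = isTRUE(strict), quantile = quantile,
                 seed = as.integer(seed),
                 include_termini = isTRUE(include_termini),
                 distinct_clusters = isTRUE(distinct_clusters),
                 scheme = scheme, search = search),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' The on-disk form round-trips losslessly; the substitution matrix is
#' stored by name and re-loaded from the package's bundled tables.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the reconstructed
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config[setdiff(names(config), c("scheme", "search"))]
  flat$scheme <- config$scheme[c("matrix_name", "gap_open", "gap_extend",
                                 "lambda", "K", "effective_search_space")]
  flat$search <- unclass(config$search)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sch <- do.call(scoring_scheme, y$scheme[!vapply(y$scheme, is.null,
                                                  logical(1))])
  srch <- do.call(search_config, y$search)
  y$scheme <- NULL; y$search <- NULL
  do.call(pipeline_config, c(y, list(scheme = sch, search = srch)))
}

#' Run the full coding-region scan
#'
#' Orchestrates regions -> six-frame translation -> low-stringency search
#' -> accumulation profiles -> peak calling, and writes the standard
#' outputs to `config$out_dir`: `regions.bed`, six per-frame bedGraph
#' profile tracks, `peaks.bed`, `peaks.gff3`, a per-region `summary.tsv`
#' (max profile height per frame and significant-peak count), the echoed
#' `config.yaml` and a `run.log`.  Outputs are identical for identical
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `regions`, `translations`, `hits`,
#'   `profiles`, `peaks`, `summary` and `config`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  genome <- load_genome(config$genome)
  regions <- extract_inter_exon_regions(config$annotation, genome,
                                        config$include_termini)
  note("regions: ", nrow(regions), " inter-exon region(s) (",
       sum(regions$source == "intergenic"), " intergenic, ",
       sum(regions$source == "intron"), " intronic)")
  scanned <- scan_regions(regions, config, note)
  write_scan_outputs(regions, scanned, config, log)
  invisible(c(list(regions = regions), scanned, list(config = config)))
}

# translate + search + profile + call peaks over a region table
scan_regions <- function(regions, config, note = function(...) NULL) {
  db <- if (!is.null(config$protein_db))
    load_protein_db(config$protein_db) else NULL
  translations <- list(); profiles <- list(); hits_all <- list()
  peaks <- list(); summary <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    tr <- six_frame_translate(reg)
    hits <- if (!is.null(db)) {
      search_hits(tr, db, config$scheme, config$search)
    } else {
      parse_external_hits(config$hits_file, tr, config$search)
    }
    maxima <- integer(6)
    for (k in 1:6) {
      t <- tr[[k]]
      p <- accumulate_profile(hits[hits$query_id == t$frame_id, ,
                                   drop = FALSE], t,
                              config$distinct_clusters)
      maxima[k] <- if (length(p$counts)) max(p$counts) else 0L
      profiles[[t$frame_id]] <- p
      pk <- call_peaks(p, t, config$cutoff, config$merge_gap,
                       config$min_length, config$strict)
      if (nrow(pk)) peaks[[t$frame_id]] <- pk
    }
    n_sig <- sum(vapply(tr, function(t) {
      pk <- peaks[[t$frame_id]]
      if (is.null(pk)) 0L else nrow(pk)
    }, integer(1)))
    summary[[i]] <- data.frame(
      region_id = reg$region_id, source = reg$source,
      length = reg$end - reg$start,
      t(stats::setNames(maxima, paste0("max_frame", 1:6))),
      n_significant_peaks = n_sig, stringsAsFactors = FALSE)
    translations[[reg$region_id]] <- tr
    hits_all[[reg$region_id]] <- hits
    note("scanned ", reg$region_id, ": ", nrow(hits), " hit(s), ",
         n_sig, " significant peak(s)")
  }
  list(translations = translations,
       hits = do.call(rbind, c(unname(hits_all), list(empty_hits()))),
       profiles = profiles,
       peaks = do.call(rbind, c(unname(peaks), list(empty_peaks()))),
       summary = do.call(rbind, summary))
}

write_scan_outputs <- function(regions, scanned, config, log) {
  out <- config$out_dir
  write_regions_bed(regions, file.path(out, "regions.bed"))
  write_profile_bedgraph(scanned$profiles, scanned$translations, out)
  write_peaks_bed(scanned$peaks, file.path(out, "peaks.bed"))
  write_peaks_gff3(scanned$peaks, file.path(out, "peaks.gff3"))
  utils::write.table(scanned$summary, file.path(out, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pipeline_config(config, file.path(out, "config.yaml"))
  writeLines(log, file.path(out, "run.log"))
}

#' Run the shuffled-sequence control stage
#'
#' Shuffles every scanned region `n_shuffles` times, re-runs the scan on
#' the shuffled controls at the same cutoff, and reports per-control
#' maximum heights and significant-peak counts together with the
#' true-positive-fraction estimate (significant regions in the real scan
#' vs significant peaks in the controls).  When the real scan has no
#' significant region the estimate is reported as `NA`.
#'
#' @param scan Result of [run_scan()].
#' @param n_shuffles Shuffled replicates per region.
#' @param seed Integer seed; every shuffle seed is derived from it and
#'   logged.
#' @return Invisibly, a list with `summary` (per-control table),
#'   `peaks`, `n_significant_real`, `n_significant_shuffled` and
#'   `true_positive_fraction`.
#' @export
run_control <- function(scan, n_shuffles = 1L, seed = 1L) {
  if (is.null(scan$summary) || is.null(scan$regions))
    stop("run_control requires the result of run_scan()")
  config <- scan$config
  log <- character(0)
  controls <- list()
  for (r in seq_len(n_shuffles)) {
    s <- as.integer(seed) + (r - 1L) * nrow(scan$regions)
    controls[[r]] <- shuffle_region(scan$regions, s)
    log <- c(log, paste0("shuffle round ", r, ": seeds ", s, "..",
                         s + nrow(scan$regions) - 1L))
  }
  controls <- do.call(rbind, controls)
  ctl <- scan_regions(controls, config)
  n_real <- sum(scan$summary$n_significant_peaks > 0L)
  n_shuf <- sum(ctl$summary$n_significant_peaks)
  tpf <- if (n_real > 0L && n_shuf <= n_real) {
    estimate_true_positive_fraction(n_real, n_shuf)
  } else NA_real_
  log <- c(log, paste0("significant regions (real scan): ", n_real),
           paste0("significant peaks (shuffled controls): ", n_shuf),
           paste0("true-positive fraction: ",
                  if (is.na(tpf)) "not applicable"
                  else sprintf("%.3f", tpf)))
  out <- config$out_dir
  utils::write.table(ctl$summary, file.path(out, "control_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(log, sep = "\n")
  con <- file(file.path(out, "run.log"), "a")
  writeLines(log, con); close(con)
  invisible(list(summary = ctl$summary, peaks = ctl$peaks,
                 n_significant_real = n_real,
                 n_significant_shuffled = n_shuf,
                 true_positive_fraction = tpf))
}
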