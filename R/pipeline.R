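#' Process selected movies through histograms, quartiles, fit, occupancies
#'
#' Core analysis chain shared by [cli_process()] and the validation
#' harnesses: per-movie selection, pooled display histograms, ensemble
#' averaging with SEM, cumulative-count quartiles, the fixed-mean trimodal
#' fit, and Simpson's-rule component occupancies.
#'
#' @param movies List of movies, each a list of raw [fret_trace()] objects.
#' @param criteria,params Selection and correction settings.
#' @param window_frames,bin_width,range Histogram settings.
#' @param means Fixed trimodal component means.
#' @param shared_sigma Share one Gaussian width across components.
#' @param combine_movies If `TRUE`, all movies are pooled into a single
#'   histogram before averaging (used when per-movie trace counts are low).
#' @return A list: `report` (per-trace QC tibble), `movie_summary`,
#'   `histograms` (per movie), `ensemble`, `quartiles`, `fit`,
#'   `occupancies`.
#' @export
analyze_movies <- function(movies, criteria = selection_criteria(),
                           params = correction_params(),
                           window_frames = 50, bin_width = 0.02,
                           range = c(-0.1, 1.1),
                           means = c(0.3, 0.5, 0.7), shared_sigma = TRUE,
                           combine_movies = FALSE) {
  if (length(movies) == 0L) abort_smfret("no movies to analyze")
  selections <- lapply(movies, select_traces, criteria = criteria,
                       params = params)
  report <- do.call(rbind, lapply(selections, `[[`, "report"))
  passing <- lapply(selections, `[[`, "traces")
  if (sum(lengths(passing)) == 0L) {
    summary <- qc_movie_summary(report)
    abort_smfret(
      "all traces rejected by selection; per-criterion pass counts:\n",
      paste(utils::capture.output(print(as.data.frame(summary))),
            collapse = "\n"))
  }
  if (combine_movies) passing <- list(unlist(passing, recursive = FALSE))
  hists <- lapply(passing, trace_histogram, window_frames = window_frames,
                  bin_width = bin_width, range = range)
  ens <- average_histograms(hists)
  quart <- quartile_summary(hists)
  fit <- fit_trimodal(ens, means = means, shared_sigma = shared_sigma)
  occ <- component_occupancies(fit)
  list(report = report, movie_summary = qc_movie_summary(report),
       histograms = hists, ensemble = ens, quartiles = quart,
       fit = fit, occupancies = occ)
}

#' Simulate movies and write trace files
#'
#' Writes one trace file per movie plus a simulation manifest and a run log
#' (the fully resolved configuration and seed) into `out_dir`.
#'
#' @param config Path to a YAML run configuration, or a resolved config
#'   list from [read_run_config()], or `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `trace_files` and `manifest`.
#' @export
cli_simulate <- function(config = NULL, out_dir = ".") {
  cfg <- if (is.list(config)) config else read_run_config(config)
  s <- cfg$simulate
  if (s$n_movies < 1) abort_smfret("config error: simulate.n_movies must be >= 1")
  if (s$n_traces < 1) abort_smfret("config error: simulate.n_traces must be >= 1")
  model <- condition_model(s$subtype, s$probe_site, s$ligand_condition)
  phys <- config_photophysics(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(s$n_movies)
  manifests <- vector("list", s$n_movies)
  for (m in seq_len(s$n_movies)) {
    sim <- simulate_movie(model, s$n_traces, phys, n_frames = s$n_frames,
                          movie_id = sprintf("movie%d", m),
                          seed = derive_seed(s$seed, 1000 + m))
    files[m] <- file.path(out_dir, sprintf("movie%d.traces.tsv", m))
    write_traces(sim$traces, files[m])
    manifests[[m]] <- sim$manifest
  }
  manifest <- do.call(rbind, manifests)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_run_log(cfg, file.path(out_dir, "simulate.log"),
                c(sprintf("master seed: %s", s$seed),
                  sprintf("wrote %d trace file(s)", length(files))))
  invisible(list(trace_files = files, manifest = manifest))
}

#' Process trace files into histograms, quartiles, and occupancies
#'
#' Runs selection, ensemble histograms, quartiles, the trimodal fit, and
#' occupancies on previously written trace files, and exports every result
#' as a tab-separated table in `out_dir`.
#'
#' @param trace_files Character vector of trace file paths (>= 1).
#' @param config As in [cli_simulate()].
#' @param out_dir Output directory.
#' @return Invisibly, the [analyze_movies()] result list.
#' @export
cli_process <- function(trace_files, config = NULL, out_dir = ".") {
  if (length(trace_files) < 1L) abort_smfret("need at least one trace file")
  cfg <- if (is.list(config)) config else read_run_config(config)
  movies <- lapply(trace_files, read_traces)
  res <- analyze_movies(
    movies, criteria = config_criteria(cfg), params = config_correction(cfg),
    window_frames = cfg$histogram$window_frames,
    bin_width = cfg$histogram$bin_width,
    range = c(cfg$histogram$range_min, cfg$histogram$range_max),
    means = c(cfg$fit$mean_low, cfg$fit$mean_mid, cfg$fit$mean_high),
    shared_sigma = cfg$fit$shared_sigma,
    combine_movies = cfg$histogram$combine_movies)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_histogram_table(res$ensemble, file.path(out_dir, "ensemble_histogram.tsv"))
  utils::write.table(res$quartiles$per_movie,
                     file.path(out_dir, "quartiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fit_df <- data.frame(component = c("low", "mid", "high"),
                       mean = res$fit$means, amplitude = res$fit$amplitudes,
                       sigma = res$fit$sigmas,
                       occupancy_percent = as.numeric(res$occupancies))
  utils::write.table(fit_df, file.path(out_dir, "trimodal_fit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  curve_df <- data.frame(bin_center = res$fit$grid, fitted = res$fit$fitted)
  utils::write.table(curve_df, file.path(out_dir, "fitted_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(cfg, file.path(out_dir, "process.log"),
                c(sprintf("traces in: %d", nrow(res$report)),
                  sprintf("traces passing: %d", sum(res$report$pass))))
  invisible(res)
}

#' Predict FRET efficiencies from distances or a coordinate file
#'
#' Either converts a numeric list of donor-acceptor distances, or measures
#' one residue-pair distance from a PDB file, and reports the expected
#' efficiency from the Forster relation.
#'
#' @param distances Numeric vector of distances in Angstrom (optional).
#' @param structure_file Optional PDB file; requires `sel_a` and `sel_b`.
#' @param sel_a,sel_b [residue_selector()] objects for the structure file.
#' @param r0 Forster radius in Angstrom; default 51 (AF555/AF647).
#' @param out_file Optional path for a tab-separated output table.
#' @return Tibble with columns `pair`, `distance_A`, `predicted_fret`.
#' @export
cli_predict_fret <- function(distances = NULL, structure_file = NULL,
                             sel_a = NULL, sel_b = NULL, r0 = 51,
                             out_file = NULL) {
  rows <- list()
  if (!is.null(distances)) {
    rows <- c(rows, list(tibble::tibble(
      pair = sprintf("distance_%g", distances),
      distance_A = as.numeric(distances),
      predicted_fret = fret_from_distance(distances, r0))))
  }
  if (!is.null(structure_file)) {
    if (is.null(sel_a) || is.null(sel_b))
      abort_smfret("a structure file requires both `sel_a` and `sel_b`")
    d <- residue_pair_distance(structure_file, sel_a, sel_b)
    rows <- c(rows, list(tibble::tibble(
      pair = paste(format(sel_a), "<->", format(sel_b)),
      distance_A = d, predicted_fret = fret_from_distance(d, r0))))
  }
  if (length(rows) == 0L)
    abort_smfret("provide `distances` and/or a `structure_file`")
  out <- do.call(rbind, rows)
  if (!is.null(out_file)) {
    utils::write.table(out, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

# internal: run log with the fully resolved configuration
write_run_log <- function(cfg, path, extra = character()) {
  writeLines(c(sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               extra, "resolved configuration:",
               paste0("  ", config_log_lines(cfg))), path)
  invisible(path)
}
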