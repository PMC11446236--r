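#' Write traces to a columnar trace file
#'
#' A plain tab-separated text format, diffable and exact: one header line
#' of key-value pairs (`movie_id`, `frame_interval_s`, `n_traces`), then
#' per-trace blocks — a `>trace_id` line followed by rows
#' `frame_index<TAB>donor<TAB>acceptor` with frame indices contiguous from
#' 0. Intensities are written with 17 significant digits so that
#' `read_traces(write_traces(x))` round-trips finite values exactly.
#'
#' @param traces List of [fret_trace()] objects from one movie.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (length(traces) == 0L) abort_smfret("no traces to write")
  movie_id <- traces[[1L]]$movie_id
  frame_interval <- traces[[1L]]$frame_interval
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("movie_id\t%s\tframe_interval_s\t%s\tn_traces\t%d",
                     movie_id, format(frame_interval, digits = 17),
                     length(traces)), con)
  for (tr in traces) {
    writeLines(paste0(">", tr$trace_id), con)
    n <- length(tr$donor)
    writeLines(sprintf("%d\t%.17g\t%.17g", seq_len(n) - 1L,
                       tr$donor, tr$acceptor), con)
  }
  invisible(path)
}

#' Read a columnar trace file
#'
#' @param path Path written by [write_traces()].
#' @return List of [fret_trace()] objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort_smfret("trace file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) abort_smfret("empty or truncated trace file: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) %% 2L != 0L)
    abort_smfret("malformed header in ", path)
  meta <- stats::setNames(hdr[seq(2L, length(hdr), by = 2L)],
                          hdr[seq(1L, length(hdr), by = 2L)])
  for (key in c("movie_id", "frame_interval_s", "n_traces"))
    if (!key %in% names(meta))
      abort_smfret("trace file header missing key `", key, "` in ", path)
  movie_id <- meta[["movie_id"]]
  frame_interval <- as.numeric(meta[["frame_interval_s"]])
  n_declared <- as.integer(meta[["n_traces"]])

  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L)
    abort_smfret("no trace blocks in ", path)
  if (length(starts) != n_declared)
    abort_smfret(sprintf("trace file %s declares %d traces but contains %d",
                         path, n_declared, length(starts)))
  ends <- c(starts[-1L] - 1L, length(lines))
  traces <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- sub("^>", "", lines[starts[i]])
    block <- lines[(starts[i] + 1L):ends[i]]
    block <- block[nzchar(block)]
    if (length(block) == 0L)
      abort_smfret("trace block `", id, "` in ", path, " has no frames")
    parts <- strsplit(block, "\t", fixed = TRUE)
    mat <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
    if (any(mat[, 1L] != seq_len(nrow(mat)) - 1L))
      abort_smfret("non-contiguous frame indices in trace `", id, "` of ", path)
    traces[[i]] <- fret_trace(mat[, 2L], mat[, 3L],
                              frame_interval = frame_interval,
                              movie_id = movie_id, trace_id = id)
  }
  traces
}

#' Write a simulation manifest
#'
#' @param manifests Tibble (rows from [simulate_movie()] manifests).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifests, path) {
  utils::write.table(manifests, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------

default_run_config <- function() {
  list(
    simulate = list(
      subtype = "GluN2A", probe_site = "LBD-D677",
      ligand_condition = "full_agonist",
      n_traces = 100, n_movies = 4, n_frames = 800, seed = 1,
      total_intensity = 1000, noise_sd = 100, crosstalk = 0.15,
      acceptor_scaling = 1.2, mean_donor_bleach_frames = 600,
      mean_acceptor_bleach_frames = 400, background = 0),
    qc = list(
      crosstalk = 0.15, donor_scaling = 1, acceptor_scaling = 1.2,
      min_fret_lifetime_frames = 50, fret_alive_threshold = 0.125,
      max_bleach_steps_per_channel = 1, max_total_intensity_cv = 0.20,
      max_channel_correlation = -0.2),
    histogram = list(
      window_frames = 50, bin_width = 0.02,
      range_min = -0.1, range_max = 1.1, combine_movies = FALSE),
    fit = list(
      mean_low = 0.3, mean_mid = 0.5, mean_high = 0.7,
      shared_sigma = TRUE),
    forster = list(r0 = 51))
}

#' Read and validate a YAML run configuration
#'
#' The file may contain any subset of the sections `simulate`, `qc`,
#' `histogram`, `fit`, `forster`; omitted keys take their documented
#' defaults and unknown keys are rejected by name.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return Nested list of fully resolved configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort_smfret("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  for (section in names(user)) {
    if (!section %in% names(cfg))
      abort_smfret("unknown config section `", section, "`; valid: ",
                   paste(names(cfg), collapse = ", "))
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        abort_smfret("unknown config key `", section, ".", key, "`; valid: ",
                     paste(names(cfg[[section]]), collapse = ", "))
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

config_photophysics <- function(cfg) {
  s <- cfg$simulate
  photophysics(total_intensity = s$total_intensity, noise_sd = s$noise_sd,
               crosstalk = s$crosstalk, acceptor_scaling = s$acceptor_scaling,
               mean_donor_bleach_frames = s$mean_donor_bleach_frames,
               mean_acceptor_bleach_frames = s$mean_acceptor_bleach_frames,
               background = s$background)
}

config_criteria <- function(cfg) {
  q <- cfg$qc
  selection_criteria(
    min_fret_lifetime_frames = q$min_fret_lifetime_frames,
    fret_alive_threshold = q$fret_alive_threshold,
    max_bleach_steps_per_channel = q$max_bleach_steps_per_channel,
    max_total_intensity_cv = q$max_total_intensity_cv,
    max_channel_correlation = q$max_channel_correlation)
}

config_correction <- function(cfg) {
  q <- cfg$qc
  correction_params(crosstalk = q$crosstalk, donor_scaling = q$donor_scaling,
                    acceptor_scaling = q$acceptor_scaling)
}

# internal: flatten the resolved config into "section.key: value" lines
config_log_lines <- function(cfg) {
  unlist(lapply(names(cfg), function(section)
    vapply(names(cfg[[section]]), function(key)
      sprintf("%s.%s: %s", section, key,
              paste(format(cfg[[section]][[key]]), collapse = ", ")), "")))
}
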