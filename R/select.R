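#' Trace selection criteria
#'
#' Automated counterparts of the standard manual smFRET selection rules:
#' single-step bleaching of each fluorophore, a minimum FRET lifetime,
#' constant total fluorescence before bleaching, and global anti-correlation
#' between donor and acceptor. The lifetime threshold (> 50 frames) is the
#' published selection setting; the constancy and anti-correlation cutoffs
#' are explicit, configurable defaults standing in for manual curation.
#'
#' @param min_fret_lifetime_frames Trace passes only if its FRET lifetime
#'   strictly exceeds this; default 50.
#' @param fret_alive_threshold Efficiency above which a frame counts as
#'   FRET-active; default 0.125.
#' @param max_bleach_steps_per_channel Maximum accepted downward steps per
#'   channel; default 1 (single-molecule evidence). At least one channel
#'   must bleach within the recording.
#' @param max_total_intensity_cv Maximum coefficient of variation of
#'   donor + acceptor over pre-bleach frames; default 0.20.
#' @param max_channel_correlation Pearson correlation of donor vs acceptor
#'   over pre-bleach frames must be at or below this; default -0.2.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_fret_lifetime_frames = 50,
                               fret_alive_threshold = 0.125,
                               max_bleach_steps_per_channel = 1,
                               max_total_intensity_cv = 0.20,
                               max_channel_correlation = -0.2) {
  check_number(min_fret_lifetime_frames, "min_fret_lifetime_frames", lower = 0)
  check_number(fret_alive_threshold, "fret_alive_threshold")
  check_number(max_bleach_steps_per_channel, "max_bleach_steps_per_channel",
               lower = 0)
  check_number(max_total_intensity_cv, "max_total_intensity_cv", lower = 0)
  check_number(max_channel_correlation, "max_channel_correlation")
  structure(
    list(min_fret_lifetime_frames = min_fret_lifetime_frames,
         fret_alive_threshold = fret_alive_threshold,
         max_bleach_steps_per_channel = max_bleach_steps_per_channel,
         max_total_intensity_cv = max_total_intensity_cv,
         max_channel_correlation = max_channel_correlation),
    class = "selection_criteria")
}

#' Correct, screen, and select traces
#'
#' Applies, per trace: channel correction, downward-step bleach detection in
#' each channel (at most `max_bleach_steps_per_channel` accepted steps each,
#' and at least one channel must bleach within the recording), FRET lifetime
#' above threshold, coefficient of variation of total intensity over
#' pre-bleach frames at or below threshold, and Pearson donor-acceptor
#' correlation over pre-bleach frames at or below threshold. A trace passes
#' iff every criterion passes. Passing traces are returned corrected, with
#' their per-frame efficiency in `$fret` and detected bleach frames in
#' `$bleach_frames`.
#'
#' @param traces List of raw [fret_trace()] objects (may be empty).
#' @param criteria A [selection_criteria()] object.
#' @param params A [correction_params()] object.
#' @return A list with `traces` (passing, corrected, with `$fret`) and
#'   `report` (tibble: one row per input trace with per-criterion flags,
#'   detected bleach frames, lifetime, CV, and correlation).
#' @export
select_traces <- function(traces, criteria = selection_criteria(),
                          params = correction_params()) {
  stopifnot(inherits(criteria, "selection_criteria"),
            inherits(params, "correction_params"))
  rows <- vector("list", length(traces))
  keep <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    res <- qc_one_trace(traces[[i]], criteria, params)
    rows[[i]] <- res$row
    if (res$row$pass) keep[[i]] <- res$trace
  }
  report <- if (length(rows)) do.call(rbind, lapply(rows, as_tibble)) else
    empty_qc_report()
  list(traces = Filter(Negate(is.null), keep), report = report)
}

qc_one_trace <- function(trace, criteria, params) {
  stopifnot(inherits(trace, "fret_trace"))
  corrected <- correct_trace(trace, params)
  d_step <- detect_bleach_step(corrected$donor)
  a_step <- detect_bleach_step(corrected$acceptor)

  pass_single_step <-
    d_step$n_steps <= criteria$max_bleach_steps_per_channel &&
    a_step$n_steps <= criteria$max_bleach_steps_per_channel &&
    (d_step$n_steps >= 1L || a_step$n_steps >= 1L)

  e <- suppressWarnings(
    compute_fret(corrected, d_step$step_frame, a_step$step_frame))
  lifetime <- fret_lifetime(e, criteria$fret_alive_threshold)
  pass_lifetime <- lifetime > criteria$min_fret_lifetime_frames

  pre <- seq_len(min(
    suppressWarnings(min(d_step$step_frame, a_step$step_frame, na.rm = TRUE)),
    length(corrected$donor)))
  total <- corrected$donor[pre] + corrected$acceptor[pre]
  cv <- if (length(pre) >= 2L && mean(total) > 0)
    stats::sd(total) / mean(total) else NA_real_
  pass_cv <- !is.na(cv) && cv <= criteria$max_total_intensity_cv

  rho <- if (length(pre) >= 3L &&
             stats::sd(corrected$donor[pre]) > 0 &&
             stats::sd(corrected$acceptor[pre]) > 0)
    stats::cor(corrected$donor[pre], corrected$acceptor[pre]) else NA_real_
  pass_anticorr <- !is.na(rho) && rho <= criteria$max_channel_correlation

  pass <- pass_single_step && pass_lifetime && pass_cv && pass_anticorr

  row <- list(
    movie_id = trace$movie_id, trace_id = trace$trace_id,
    donor_bleach = as.integer(d_step$step_frame),
    acceptor_bleach = as.integer(a_step$step_frame),
    donor_steps = d_step$n_steps, acceptor_steps = a_step$n_steps,
    fret_lifetime = lifetime, total_cv = cv, channel_cor = rho,
    pass_single_step = pass_single_step, pass_lifetime = pass_lifetime,
    pass_constant_total = pass_cv, pass_anticorrelation = pass_anticorr,
    pass = pass)

  if (pass) {
    corrected$fret <- e
    corrected$bleach_frames <- c(donor = d_step$step_frame,
                                 acceptor = a_step$step_frame)
  }
  list(row = row, trace = corrected)
}

empty_qc_report <- function() {
  tibble::tibble(
    movie_id = character(), trace_id = character(),
    donor_bleach = integer(), acceptor_bleach = integer(),
    donor_steps = integer(), acceptor_steps = integer(),
    fret_lifetime = integer(), total_cv = double(), channel_cor = double(),
    pass_single_step = logical(), pass_lifetime = logical(),
    pass_constant_total = logical(), pass_anticorrelation = logical(),
    pass = logical())
}

#' Per-movie summary of a QC report
#'
#' @param report The per-trace report from [select_traces()].
#' @return Tibble with one row per movie: counts passing each criterion.
#' @export
qc_movie_summary <- function(report) {
  if (nrow(report) == 0L) {
    return(tibble::tibble(movie_id = character(), n_traces = integer(),
                          n_single_step = integer(), n_lifetime = integer(),
                          n_constant_total = integer(),
                          n_anticorrelation = integer(), n_pass = integer()))
  }
  by <- split(report, report$movie_id)
  do.call(rbind, lapply(by, function(d) tibble::tibble(
    movie_id = d$movie_id[1L], n_traces = nrow(d),
    n_single_step = sum(d$pass_single_step),
    n_lifetime = sum(d$pass_lifetime),
    n_constant_total = sum(d$pass_constant_total),
    n_anticorrelation = sum(d$pass_anticorrelation),
    n_pass = sum(d$pass))))
}
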