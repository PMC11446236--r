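#' Bin grid for display histograms
#'
#' Bin width 0.02 over \[-0.1, 1.1\]; the range accommodates noise-driven
#' excursions of the efficiency outside \[0, 1\] without clipping.
#'
#' @param bin_width Bin width in FRET units; default 0.02.
#' @param range Two-element range; default `c(-0.1, 1.1)`.
#' @return Numeric vector of bin edges.
#' @export
fret_bin_edges <- function(bin_width = 0.02, range = c(-0.1, 1.1)) {
  seq(range[1L], range[2L], by = bin_width)
}

bin_centers <- function(edges) (edges[-1L] + edges[-length(edges)]) / 2

#' Pooled FRET histogram of one movie's selected traces
#'
#' Pools the first `window_frames` valid (pre-bleach, non-`NA`) efficiency
#' values of each selected trace and bins them on the display grid,
#' normalizing to fractions of total counts. Using a fixed leading window
#' per trace matches display-histogram convention and keeps the result
#' deterministic.
#'
#' @param traces Selected traces from [select_traces()] (each with `$fret`).
#' @param window_frames Leading valid frames pooled per trace; default 50.
#' @param bin_width,range Passed to [fret_bin_edges()].
#' @param movie_id Identifier; defaults to the first trace's movie.
#' @return An object of class `fret_histogram`: list with `bin_edges`,
#'   `values` (fractions summing to 1), `n_traces`, `movie_id`.
#' @export
trace_histogram <- function(traces, window_frames = 50,
                            bin_width = 0.02, range = c(-0.1, 1.1),
                            movie_id = NULL) {
  edges <- fret_bin_edges(bin_width, range)
  pooled <- unlist(lapply(traces, function(tr) {
    if (is.null(tr$fret))
      abort_smfret("traces must carry $fret; run select_traces() first")
    utils::head(tr$fret[!is.na(tr$fret)], window_frames)
  }))
  if (is.null(movie_id))
    movie_id <- if (length(traces)) traces[[1L]]$movie_id else "movie"
  if (length(pooled) == 0L) {
    warning("no valid frames to histogram for ", movie_id, call. = FALSE)
    return(structure(list(bin_edges = edges,
                          values = numeric(length(edges) - 1L),
                          n_traces = 0L, movie_id = movie_id),
                     class = "fret_histogram"))
  }
  counts <- tabulate(findInterval(pooled, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, values = counts / sum(counts),
                 n_traces = length(traces), movie_id = movie_id),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("<fret_histogram> %s: %d traces, %d bins of width %.3g\n",
              x$movie_id, x$n_traces, length(x$values),
              x$bin_edges[2L] - x$bin_edges[1L]))
  invisible(x)
}

#' Average per-movie histograms into an ensemble histogram
#'
#' Elementwise mean and standard error of the mean across movies. Movies
#' are technical replicates and weighted equally regardless of trace count.
#'
#' @param histograms List of [trace_histogram()] results on identical grids.
#' @return An object of class `ensemble_histogram`: `bin_edges`, `mean`,
#'   `sem` (elementwise sample s.d. / sqrt(n_movies)), `n_movies`.
#' @export
average_histograms <- function(histograms) {
  if (length(histograms) < 1L)
    abort_smfret("need at least one histogram to average")
  edges <- histograms[[1L]]$bin_edges
  for (h in histograms) {
    if (!inherits(h, "fret_histogram"))
      abort_smfret("inputs must be fret_histogram objects")
    if (length(h$bin_edges) != length(edges) ||
        max(abs(h$bin_edges - edges)) > 1e-12)
      abort_smfret("histograms are on mismatched bin grids")
  }
  vals <- do.call(rbind, lapply(histograms, `[[`, "values"))
  n <- nrow(vals)
  mu <- colMeans(vals)
  sem <- if (n > 1L) apply(vals, 2L, stats::sd) / sqrt(n) else
    numeric(ncol(vals))
  structure(list(bin_edges = edges, mean = mu, sem = sem, n_movies = n),
            class = "ensemble_histogram")
}

#' @export
print.ensemble_histogram <- function(x, ...) {
  cat(sprintf("<ensemble_histogram> %d movies, %d bins\n",
              x$n_movies, length(x$mean)))
  invisible(x)
}

#' Cumulative-count quartile summary of per-movie histograms
#'
#' For each movie the bins are walked in increasing FRET order accumulating
#' normalized counts; the p-quartile is the center of the first bin whose
#' cumulative sum *strictly* exceeds p. The three quartiles are then
#' averaged across movies.
#'
#' @param histograms List of per-movie [trace_histogram()] results.
#' @return A list with `per_movie` (tibble: movie_id, q25, q50, q75) and
#'   `mean` (named vector of across-movie averages). All-zero histograms
#'   yield `NA` quartiles.
#' @export
quartile_summary <- function(histograms) {
  rows <- lapply(histograms, function(h) {
    centers <- bin_centers(h$bin_edges)
    tot <- sum(h$values)
    if (tot <= 0) {
      q <- c(NA_real_, NA_real_, NA_real_)
    } else {
      cum <- cumsum(h$values / tot)
      q <- vapply(c(0.25, 0.50, 0.75), function(p) {
        i <- which(cum > p)[1L]
        if (is.na(i)) NA_real_ else centers[i]
      }, 0)
    }
    tibble::tibble(movie_id = h$movie_id, q25 = q[1L], q50 = q[2L], q75 = q[3L])
  })
  per_movie <- do.call(rbind, rows)
  list(per_movie = per_movie,
       mean = c(q25 = mean(per_movie$q25), q50 = mean(per_movie$q50),
                q75 = mean(per_movie$q75)))
}

#' Fraction of ensemble histogram mass below a FRET cutoff
#'
#' Direct occupancy measure for well-separated states: the share of the
#' mean histogram in bins whose centers lie strictly below `cutoff`. Used
#' e.g. to quantify the low-FRET "splayed" state of the NTD probe, whose
#' ~0.2 peak lies outside the fixed trimodal basis.
#'
#' @param ensemble An [average_histograms()] result.
#' @param cutoff FRET efficiency cutoff.
#' @return Fraction in \[0, 1\].
#' @export
histogram_mass_below <- function(ensemble, cutoff) {
  stopifnot(inherits(ensemble, "ensemble_histogram"))
  centers <- bin_centers(ensemble$bin_edges)
  sum(ensemble$mean[centers < cutoff]) / sum(ensemble$mean)
}

#' Export an ensemble histogram as a tab-separated table
#'
#' @param ensemble An [average_histograms()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_histogram_table <- function(ensemble, path) {
  df <- data.frame(bin_center = bin_centers(ensemble$bin_edges),
                   mean = ensemble$mean, sem = ensemble$sem)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
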