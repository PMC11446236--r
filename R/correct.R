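#' Channel correction parameters
#'
#' Defaults reproduce the pipeline's correction constants: crosstalk 0.15,
#' donor scaling 1.0, acceptor scaling 1.2.
#'
#' @param crosstalk Fraction of donor emission detected in the acceptor
#'   channel, subtracted after scaling; in \[0, 1).
#' @param donor_scaling,acceptor_scaling Channel gain factors (> 0).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(crosstalk = 0.15, donor_scaling = 1,
                              acceptor_scaling = 1.2) {
  check_number(crosstalk, "crosstalk", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(donor_scaling, "donor_scaling", lower = 0, strict_lower = TRUE)
  check_number(acceptor_scaling, "acceptor_scaling", lower = 0, strict_lower = TRUE)
  structure(list(crosstalk = crosstalk, donor_scaling = donor_scaling,
                 acceptor_scaling = acceptor_scaling),
            class = "correction_params")
}

#' Apply scaling and crosstalk correction to a raw trace
#'
#' Both channels are scaled first, then donor bleed-through is subtracted
#' from the acceptor: `donor' = donor_scaling * donor`;
#' `acceptor' = acceptor_scaling * acceptor - crosstalk * donor'`. This
#' order is the inverse of the photophysics embedded by [render_trace()],
#' so in the noise-free limit correction recovers the ideal channel
#' intensities exactly.
#'
#' @param trace A [fret_trace()].
#' @param params A [correction_params()] object.
#' @return The corrected [fret_trace()].
#' @export
correct_trace <- function(trace, params = correction_params()) {
  stopifnot(inherits(trace, "fret_trace"), inherits(params, "correction_params"))
  donor <- params$donor_scaling * trace$donor
  acceptor <- params$acceptor_scaling * trace$acceptor - params$crosstalk * donor
  out <- trace
  out$donor <- donor
  out$acceptor <- acceptor
  out
}

#' Detect downward photobleaching steps in an intensity channel
#'
#' Binary segmentation on the mean-shift (least-squares) cost: the split
#' giving the largest cost reduction is examined; segmentation recurses
#' where the mean change is significant, and a change-point counts as a
#' bleaching step when the *drop* (left mean minus right mean) exceeds
#' three times the robust noise scale, estimated as the median absolute
#' deviation of the first differences (scaled by 1.4826). Upward steps
#' (e.g. donor dequenching) are never counted as bleaching.
#'
#' @param intensity Numeric vector of per-frame counts, length >= 4.
#' @return A list with `step_frame` (0-based index of the first frame after
#'   the first accepted drop, i.e. the number of pre-bleach frames; `NA` if
#'   no step) and `n_steps` (number of accepted downward steps).
#' @export
detect_bleach_step <- function(intensity) {
  x <- as.numeric(intensity)
  if (length(x) < 4L) abort_smfret("need at least 4 frames to detect a step")
  scale <- stats::mad(diff(x))          # 1.4826 * MAD of first differences
  thresh <- max(3 * scale, 1e-9 * max(abs(x), 1))
  cps <- binseg_changepoints(x, 1L, length(x), thresh)
  if (length(cps)) {
    cps <- sort(cps)
    drops <- vapply(cps, function(k) segment_drop(x, cps, k), 0)
    down <- cps[drops > thresh]
  } else down <- integer(0)
  list(step_frame = if (length(down)) down[1L] else NA_integer_,
       n_steps = length(down))
}

# internal: recursive binary segmentation on x[lo..hi]; returns 0-based
# change-point positions k (split between frames k and k+1 in 0-based
# terms). A split is pursued when |mean change| exceeds `thresh`.
binseg_changepoints <- function(x, lo, hi, thresh) {
  n <- hi - lo + 1L
  if (n < 4L) return(integer(0))
  seg <- x[lo:hi]
  # candidate split after position k (1-based within segment), 2 <= k <= n-2
  cs <- cumsum(seg)
  tot <- cs[n]
  k <- 2:(n - 2L)
  mean_l <- cs[k] / k
  mean_r <- (tot - cs[k]) / (n - k)
  # cost reduction of a single mean-shift split
  gain <- (k * (n - k) / n) * (mean_l - mean_r)^2
  best <- which.max(gain)
  kb <- k[best]
  if (abs(mean_l[best] - mean_r[best]) <= thresh) return(integer(0))
  cp <- lo + kb - 1L                    # last frame of left segment (1-based)
  c(binseg_changepoints(x, lo, cp, thresh),
    cp,                                  # stored 1-based; converted by caller
    binseg_changepoints(x, cp + 1L, hi, thresh))
}

# internal: drop (left mean - right mean) at change-point k given the full
# sorted change-point set (segment means between neighboring change-points).
segment_drop <- function(x, cps, k) {
  cps <- sort(cps)
  i <- match(k, cps)
  left_start <- if (i == 1L) 1L else cps[i - 1L] + 1L
  right_end <- if (i == length(cps)) length(x) else cps[i + 1L]
  mean(x[left_start:k]) - mean(x[(k + 1L):right_end])
}

#' Per-frame FRET efficiency of a corrected trace
#'
#' `E_t = acceptor_t / (acceptor_t + donor_t)` for frames strictly before
#' the first bleaching event; frames at or after the first bleach are `NA`.
#' E is not clamped, so channel noise may push values slightly outside
#' \[0, 1\]. A pre-bleach frame with non-positive total intensity yields
#' `NA` with a warning.
#'
#' @param trace A corrected [fret_trace()].
#' @param donor_bleach,acceptor_bleach 0-based first dark frame of each
#'   channel (`NA` if the channel never bleaches within the trace).
#' @return Numeric vector of per-frame efficiencies (with `NA`s).
#' @export
compute_fret <- function(trace, donor_bleach = NA, acceptor_bleach = NA) {
  stopifnot(inherits(trace, "fret_trace"))
  n <- length(trace$donor)
  first_bleach <- suppressWarnings(min(donor_bleach, acceptor_bleach, na.rm = TRUE))
  if (!is.finite(first_bleach)) first_bleach <- n
  n_valid <- min(first_bleach, n)      # number of pre-bleach frames
  total <- trace$donor + trace$acceptor
  e <- rep(NA_real_, n)
  if (n_valid >= 1L) {
    idx <- seq_len(n_valid)
    bad <- total[idx] <= 0
    e[idx] <- trace$acceptor[idx] / total[idx]
    if (any(bad)) {
      e[idx][bad] <- NA_real_
      warning(sum(bad), " pre-bleach frame(s) with non-positive total intensity in ",
              trace$trace_id, call. = FALSE)
    }
  }
  e
}

#' FRET lifetime of a trace
#'
#' Number of frames, from the start of the trace to the first bleaching
#' event, whose efficiency exceeds the alive threshold. Traces must show a
#' FRET lifetime above the selection threshold (default > 50 frames) to be
#' retained.
#'
#' @param e Per-frame efficiency from [compute_fret()] (`NA` = post-bleach).
#' @param alive_threshold Efficiency above which a frame counts as
#'   FRET-active; default 0.125.
#' @return Integer frame count.
#' @export
fret_lifetime <- function(e, alive_threshold = 0.125) {
  sum(e > alive_threshold, na.rm = TRUE)
}
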