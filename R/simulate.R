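#' Photophysical parameters for trace simulation
#'
#' Defaults embed the correction constants of the processing pipeline
#' (crosstalk 0.15, acceptor channel scaling 1.2) as the algebraic inverse
#' of [correct_trace()], so that correction exactly recovers the ideal
#' channel intensities in the noise-free limit. Photobleaching of each
#' fluorophore is a memoryless (geometric) per-frame hazard.
#'
#' @param total_intensity Donor-excited total emission before bleaching,
#'   counts/frame.
#' @param noise_sd Additive per-channel Gaussian noise s.d., counts.
#'   Default 10% of `total_intensity` (sCMOS read-noise-dominated regime).
#' @param crosstalk Fraction of donor signal bleeding into the acceptor
#'   channel; default 0.15.
#' @param acceptor_scaling Acceptor/donor detection gain ratio; default 1.2.
#' @param mean_donor_bleach_frames,mean_acceptor_bleach_frames Mean number
#'   of frames before each fluorophore bleaches; defaults 600 / 400 so most
#'   traces survive the >50-frame FRET lifetime filter.
#' @param background Per-channel background, counts/frame.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 1000,
                         noise_sd = 0.1 * total_intensity,
                         crosstalk = 0.15,
                         acceptor_scaling = 1.2,
                         mean_donor_bleach_frames = 600,
                         mean_acceptor_bleach_frames = 400,
                         background = 0) {
  check_number(total_intensity, "total_intensity", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(crosstalk, "crosstalk", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(acceptor_scaling, "acceptor_scaling", lower = 0, strict_lower = TRUE)
  check_number(mean_donor_bleach_frames, "mean_donor_bleach_frames",
               lower = 0, strict_lower = TRUE)
  check_number(mean_acceptor_bleach_frames, "mean_acceptor_bleach_frames",
               lower = 0, strict_lower = TRUE)
  check_number(background, "background", lower = 0)
  structure(
    list(total_intensity = total_intensity, noise_sd = noise_sd,
         crosstalk = crosstalk, acceptor_scaling = acceptor_scaling,
         mean_donor_bleach_frames = mean_donor_bleach_frames,
         mean_acceptor_bleach_frames = mean_acceptor_bleach_frames,
         background = background),
    class = "photophysics")
}

#' Construct a two-channel intensity trace
#'
#' @param donor,acceptor Numeric vectors of per-frame counts, equal length.
#' @param frame_interval Seconds per frame; default 0.1 (10 frames/s).
#' @param movie_id,trace_id Identifiers.
#' @param true_state_path Optional integer state indices (simulated traces).
#' @param true_bleach_frames Optional pair `c(donor, acceptor)` giving the
#'   0-based index of the first dark frame of each fluorophore (may exceed
#'   the trace length when the fluorophore outlives the recording).
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, frame_interval = 0.1,
                       movie_id = "movie", trace_id = "trace",
                       true_state_path = NULL, true_bleach_frames = NULL) {
  if (length(donor) != length(acceptor) || length(donor) < 1L)
    abort_smfret("donor and acceptor must have identical length >= 1")
  check_number(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  structure(
    list(donor = as.numeric(donor), acceptor = as.numeric(acceptor),
         frame_interval = frame_interval,
         movie_id = movie_id, trace_id = trace_id,
         true_state_path = true_state_path,
         true_bleach_frames = true_bleach_frames),
    class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %s/%s: %d frames at %g s/frame\n",
              x$movie_id, x$trace_id, length(x$donor), x$frame_interval))
  invisible(x)
}

#' @export
length.fret_trace <- function(x) length(x$donor)

#' Draw labeling stoichiometries for receptors with two equivalent sites
#'
#' Each of the two labeling sites independently carries a donor or an
#' acceptor with probability 1/2, so a receptor is donor/acceptor (`"DA"`,
#' the only FRET-competent species) with probability 1/2, and donor/donor or
#' acceptor/acceptor with probability 1/4 each.
#'
#' @param n Number of receptors to draw.
#' @param seed Optional RNG seed for a reproducible draw.
#' @return Character vector in `{"DA", "DD", "AA"}` of length `n`.
#' @export
assign_label_stoichiometry <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  site1 <- runif(n) < 0.5          # TRUE = donor
  site2 <- runif(n) < 0.5
  ifelse(site1 & site2, "DD", ifelse(!site1 & !site2, "AA", "DA"))
}

#' Simulate a discrete-time Markov conformational state path
#'
#' Frame-resolution surrogate for conformational dynamics: from state *i*
#' the chain exits each frame with probability `1/mean_dwell_frames[i]`; on
#' exit the destination is drawn with weights proportional to
#' `occupancy_j / mean_dwell_frames_j` (self-transitions allowed). This
#' construction makes the chain's stationary distribution exactly equal to
#' the model occupancies for any dwell vector; with equal dwell times it
#' reduces to drawing destinations proportional to occupancies. The initial
#' state is drawn from the occupancies, so the path is stationary from
#' frame 1.
#'
#' @param model A [state_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Optional RNG seed.
#' @return Integer vector of state indices (1-based) of length `n_frames`.
#' @export
simulate_state_path <- function(model, n_frames, seed = NULL) {
  stopifnot(inherits(model, "state_model"))
  if (n_frames < 1) abort_smfret("`n_frames` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  occ <- model$occupancies
  if (any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
    abort_smfret("model occupancies must form a probability simplex")
  k <- nrow(model$states)
  path <- integer(n_frames)
  if (k == 1L) return(rep(1L, n_frames))
  dwell <- model$states$mean_dwell_frames
  p_exit <- 1 / dwell
  dest_w <- occ / dwell
  dest_w <- dest_w / sum(dest_w)
  s <- sample.int(k, 1L, prob = occ)
  t <- 1L
  while (t <= n_frames) {
    run <- rgeom(1L, p_exit[s]) + 1L   # frames until (and including) exit
    upto <- min(t + run - 1L, n_frames)
    path[t:upto] <- s
    t <- upto + 1L
    s <- sample.int(k, 1L, prob = dest_w)
  }
  path
}

# internal: transition matrix of the simulated chain (used by tests and
# documented for oracle comparison).
state_transition_matrix <- function(model) {
  occ <- model$occupancies
  dwell <- model$states$mean_dwell_frames
  k <- length(occ)
  p_exit <- 1 / dwell
  w <- occ / dwell
  w <- w / sum(w)
  P <- outer(p_exit, w)
  diag(P) <- diag(P) + (1 - p_exit)
  P
}

#' Render a two-channel trace from a state path
#'
#' Converts a conformational state path into donor/acceptor intensities with
#' the full photophysical structure: per-frame ideal efficiency
#' `e_t = clamp(mean_fret + width * N(0,1), 0, 1)`; geometric single-step
#' photobleaching of each fluorophore; donor dequenching to the full total
#' intensity after the acceptor bleaches; donor-to-acceptor crosstalk and
#' acceptor channel gain embedded as the algebraic inverse of
#' [correct_trace()]; and additive Gaussian noise plus background in each
#' channel.
#'
#' @param state_path Integer state indices from [simulate_state_path()].
#' @param model The [state_model()] that produced the path.
#' @param phys A [photophysics()] object.
#' @param seed Optional RNG seed.
#' @param movie_id,trace_id Identifiers stored in the trace.
#' @return A [fret_trace()] with `true_state_path`, `true_bleach_frames`,
#'   and `true_efficiency` (the realized per-frame ideal efficiency).
#' @export
render_trace <- function(state_path, model, phys = photophysics(),
                         seed = NULL, movie_id = "movie", trace_id = "trace") {
  stopifnot(inherits(model, "state_model"), inherits(phys, "photophysics"))
  n <- length(state_path)
  if (n < 1L) abort_smfret("`state_path` must be non-empty")
  if (!is.null(seed)) set.seed(seed)

  # 0-based index of the first dark frame of each fluorophore
  donor_bleach <- rgeom(1L, 1 / phys$mean_donor_bleach_frames) + 1L
  acceptor_bleach <- rgeom(1L, 1 / phys$mean_acceptor_bleach_frames) + 1L

  mu <- model$states$mean_fret[state_path]
  wd <- model$states$width[state_path]
  e_t <- pmin(pmax(mu + wd * rnorm(n), 0), 1)

  frame0 <- seq_len(n) - 1L
  donor_alive <- frame0 < donor_bleach
  acceptor_alive <- frame0 < acceptor_bleach

  total <- phys$total_intensity
  chi <- phys$crosstalk
  gam <- phys$acceptor_scaling

  donor_sig <- numeric(n)
  acceptor_sig <- numeric(n)

  both <- donor_alive & acceptor_alive
  donor_sig[both] <- total * (1 - e_t[both])
  acceptor_sig[both] <- (total * e_t[both] + chi * total * (1 - e_t[both])) / gam

  dequench <- donor_alive & !acceptor_alive
  donor_sig[dequench] <- total
  acceptor_sig[dequench] <- chi * total / gam    # bleed-through only

  donor <- donor_sig + phys$background + rnorm(n, sd = phys$noise_sd)
  acceptor <- acceptor_sig + phys$background + rnorm(n, sd = phys$noise_sd)

  out <- fret_trace(donor, acceptor,
                    movie_id = movie_id, trace_id = trace_id,
                    true_state_path = as.integer(state_path),
                    true_bleach_frames = c(donor = donor_bleach,
                                           acceptor = acceptor_bleach))
  out$true_efficiency <- e_t      # ground truth for round-trip validation
  out
}

#' Simulate one movie of FRET-competent traces
#'
#' Draws `n_traces` receptors, assigns each a labeling stoichiometry, and
#' renders a trace for every donor/acceptor (`DA`) receptor; `DD` and `AA`
#' receptors do not undergo FRET and are only counted in the manifest. All
#' randomness derives from `seed`, expanded deterministically per trace, so
#' repeated calls are bit-identical.
#'
#' @param model A [state_model()].
#' @param n_traces Number of receptors to draw (>= 1).
#' @param phys A [photophysics()] object.
#' @param n_frames Frames per trace; default 800 (80 s at 10 frames/s).
#' @param movie_id Identifier shared by the traces.
#' @param seed Integer seed.
#' @return A list with `traces` (list of [fret_trace()]) and `manifest`
#'   (one-row tibble of counts and parameters).
#' @export
simulate_movie <- function(model, n_traces, phys = photophysics(),
                           n_frames = 800, movie_id = "movie1", seed = 1) {
  stopifnot(inherits(model, "state_model"))
  if (!is.numeric(n_traces) || n_traces < 1)
    abort_smfret("`n_traces` must be >= 1")
  n_traces <- as.integer(n_traces)
  stoich <- assign_label_stoichiometry(n_traces, seed = derive_seed(seed, 0))
  da <- which(stoich == "DA")
  traces <- vector("list", length(da))
  for (j in seq_along(da)) {
    i <- da[j]
    trace_seed <- derive_seed(seed, i)
    set.seed(trace_seed)
    path <- simulate_state_path(model, n_frames)
    traces[[j]] <- render_trace(path, model, phys,
                                movie_id = movie_id,
                                trace_id = sprintf("%s_tr%04d", movie_id, i))
  }
  manifest <- tibble::tibble(
    movie_id = movie_id, seed = seed, n_requested = n_traces,
    n_DA = sum(stoich == "DA"), n_DD = sum(stoich == "DD"),
    n_AA = sum(stoich == "AA"), n_frames = n_frames,
    subtype = model$subtype, probe_site = model$probe_site,
    ligand_condition = model$ligand_condition,
    total_intensity = phys$total_intensity, noise_sd = phys$noise_sd,
    crosstalk = phys$crosstalk, acceptor_scaling = phys$acceptor_scaling,
    mean_donor_bleach_frames = phys$mean_donor_bleach_frames,
    mean_acceptor_bleach_frames = phys$mean_acceptor_bleach_frames,
    background = phys$background)
  list(traces = traces, manifest = manifest)
}
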