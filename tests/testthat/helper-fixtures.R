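# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no data files.

T0 <- 1000  # fixture total intensity, counts/frame

# Build a raw trace whose *corrected* channels equal the given ideal values,
# by inverting the default correction (donor scale 1, acceptor scale 1.2,
# crosstalk 0.15). `e` is the ideal efficiency per frame; phases are set by
# the 0-based bleach indices (acceptor first, then donor).
make_raw_trace <- function(e, acceptor_bleach = NA, donor_bleach = NA,
                           total = T0, noise_sd = 0, trace_id = "fix",
                           movie_id = "fixture", total_profile = NULL,
                           uncorrelated_noise = TRUE) {
  n <- length(e)
  tot <- if (is.null(total_profile)) rep(total, n) else total_profile
  frame0 <- seq_len(n) - 1L
  a_alive <- if (is.na(acceptor_bleach)) rep(TRUE, n) else frame0 < acceptor_bleach
  d_alive <- if (is.na(donor_bleach)) rep(TRUE, n) else frame0 < donor_bleach
  donor_c <- acceptor_c <- numeric(n)
  both <- a_alive & d_alive
  donor_c[both] <- tot[both] * (1 - e[both])
  acceptor_c[both] <- tot[both] * e[both]
  deq <- d_alive & !a_alive
  donor_c[deq] <- tot[deq]
  if (noise_sd > 0) {
    donor_c <- donor_c + rnorm(n, sd = noise_sd)
    acceptor_c <- acceptor_c +
      (if (uncorrelated_noise) rnorm(n, sd = noise_sd) else -rnorm(n, sd = noise_sd))
  }
  # invert default correction: raw_acc = (acc_c + chi * donor_c) / gamma
  fret_trace(donor_c, (acceptor_c + 0.15 * donor_c) / 1.2,
             movie_id = movie_id, trace_id = trace_id)
}

# Square-wave efficiency alternating between lo and hi every `period` frames
square_e <- function(n, lo = 0.45, hi = 0.55, period = 10) {
  ifelse(((seq_len(n) - 1L) %/% period) %% 2L == 0L, lo, hi)
}

# The six-trace defect fixture set: exactly the first trace is compliant.
defect_fixture_set <- function(seed = 42) {
  set.seed(seed)
  n <- 200L
  list(
    compliant = make_raw_trace(square_e(n), acceptor_bleach = 150,
                               donor_bleach = 180, noise_sd = 20,
                               trace_id = "compliant"),
    two_step = {
      # extra partial acceptor drop at frame 80 before the real bleach
      e <- c(rep(0.6, 80), rep(0.4, 70), rep(0, 50))
      tr <- make_raw_trace(e, acceptor_bleach = 150, donor_bleach = 180,
                           noise_sd = 20, trace_id = "two_step")
      tr
    },
    no_bleach = make_raw_trace(rep(0.5, n), noise_sd = 20,
                               trace_id = "no_bleach"),
    short_lifetime = make_raw_trace(square_e(n), acceptor_bleach = 30,
                                    donor_bleach = 180, noise_sd = 20,
                                    trace_id = "short_lifetime"),
    flat_uncorrelated = make_raw_trace(rep(0.5, n), acceptor_bleach = 150,
                                       donor_bleach = 180, noise_sd = 30,
                                       trace_id = "flat_uncorrelated"),
    # constant efficiency so that the ramp produces no spurious down-steps;
    # the defect is the drifting total intensity (CV ~0.25 pre-bleach)
    drifting = make_raw_trace(rep(0.5, n), acceptor_bleach = 150,
                              donor_bleach = 180, noise_sd = 20,
                              total_profile = seq(1000, 3000, length.out = 200),
                              trace_id = "drifting")
  )
}

# Exhaustive single change-point least-squares oracle: the split k (frames
# 1..k vs k+1..n, k returned 0-based as the first right-hand frame) that
# minimizes the two-segment squared error.
exhaustive_single_cp <- function(x) {
  n <- length(x)
  best <- list(sse = Inf, k = NA_integer_)
  for (k in 2:(n - 2L)) {
    l <- x[1:k]; r <- x[(k + 1L):n]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best$sse) best <- list(sse = sse, k = k)
  }
  best$k
}

# Exhaustive two change-point least-squares oracle (three mean segments).
exhaustive_double_cp <- function(x) {
  n <- length(x)
  best <- list(sse = Inf, k = c(NA, NA))
  for (k1 in 2:(n - 4L)) for (k2 in (k1 + 2L):(n - 2L)) {
    segs <- list(x[1:k1], x[(k1 + 1L):k2], x[(k2 + 1L):n])
    sse <- sum(vapply(segs, function(s) sum((s - mean(s))^2), 0))
    if (sse < best$sse) best <- list(sse = sse, k = c(k1, k2))
  }
  best$k
}

# A fret_trace carrying only a precomputed efficiency sequence (for
# histogram-level tests that do not need channel data).
efficiency_trace <- function(e, trace_id = "etr", movie_id = "m") {
  tr <- fret_trace(rep(1, length(e)), rep(1, length(e)),
                   movie_id = movie_id, trace_id = trace_id)
  tr$fret <- e
  tr
}

# Histogram with prescribed normalized values on the standard grid.
manual_histogram <- function(values, movie_id = "m") {
  structure(list(bin_edges = fret_bin_edges(), values = values,
                 n_traces = 1L, movie_id = movie_id),
            class = "fret_histogram")
}

# Minimal synthetic PDB writer (fixed-column ATOM records).
write_synthetic_pdb <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$atom, ifelse(is.na(a$altloc), " ", a$altloc), a$resname,
            a$chain, a$resno, a$x, a$y, a$z,
            ifelse(is.na(a$occ), 1, a$occ), 0, "C")
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(chain, resno, x, y, z, atom = "CB", resname = "ALA",
                     altloc = NA, occ = NA) {
  data.frame(chain = chain, resno = resno, x = x, y = y, z = z,
             atom = atom, resname = resname, altloc = altloc, occ = occ,
             stringsAsFactors = FALSE)
}
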