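test_that("channel correction applies scale-then-subtract arithmetic", {
  tr <- fret_trace(donor = 100, acceptor = 115)
  out <- correct_trace(tr)
  expect_equal(out$acceptor, 1.2 * 115 - 0.15 * 100)   # 123
  expect_equal(out$donor, 100)

  ident <- correction_params(crosstalk = 0, donor_scaling = 1,
                             acceptor_scaling = 1)
  tr2 <- fret_trace(donor = c(5, 10), acceptor = c(7, 3))
  out2 <- correct_trace(tr2, ident)
  expect_identical(out2$donor, tr2$donor)
  expect_identical(out2$acceptor, tr2$acceptor)

  expect_error(correction_params(acceptor_scaling = -1), "outside")
})

test_that("correction is linear in the input intensities", {
  set.seed(8)
  tr <- fret_trace(runif(50, 100, 900), runif(50, 100, 900))
  scaled <- fret_trace(3.7 * tr$donor, 3.7 * tr$acceptor)
  a <- correct_trace(scaled)
  b <- correct_trace(tr)
  expect_equal(a$donor, 3.7 * b$donor)
  expect_equal(a$acceptor, 3.7 * b$acceptor)
})

test_that("a clean single step and a constant trace are classified exactly", {
  x <- c(rep(1000, 60), rep(0, 40))
  res <- detect_bleach_step(x)
  expect_identical(res$step_frame, 60L)
  expect_identical(res$n_steps, 1L)

  res0 <- detect_bleach_step(rep(500, 100))
  expect_identical(res0$step_frame, NA_integer_)
  expect_identical(res0$n_steps, 0L)
})

test_that("bleach detection matches the exhaustive change-point oracle on clean steps", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    k <- sample(5:(n - 5), 1)
    hi <- runif(1, 200, 2000)
    lo <- runif(1, 0, hi * 0.5)
    x <- c(rep(hi, k), rep(lo, n - k))
    res <- detect_bleach_step(x)
    expect_identical(res$n_steps, 1L)
    expect_identical(res$step_frame, exhaustive_single_cp(x))
    expect_identical(res$step_frame, k)
  }
})

test_that("a noisy two-step staircase yields two steps at the oracle positions", {
  set.seed(7)
  x <- c(rep(1000, 40), rep(500, 30), rep(0, 30)) + rnorm(100, sd = 20)
  res <- detect_bleach_step(x)
  expect_identical(res$n_steps, 2L)
  oracle <- exhaustive_double_cp(x)
  expect_lte(abs(res$step_frame - oracle[1]), 1)
})

test_that("upward steps are never counted as bleaching", {
  x <- c(rep(400, 50), rep(1000, 50), rep(0, 50))   # dequench then bleach
  res <- detect_bleach_step(x)
  expect_identical(res$n_steps, 1L)
  expect_identical(res$step_frame, 100L)
})

test_that("per-frame efficiency follows the channel ratio and bleach masking", {
  tr <- fret_trace(donor = c(100, 100, 100, 100),
                   acceptor = c(100, 0, 300, 100))
  e <- compute_fret(tr, donor_bleach = 3, acceptor_bleach = NA)
  expect_equal(e[1:3], c(0.5, 0, 0.75))
  expect_true(is.na(e[4]))

  tr0 <- fret_trace(donor = c(100, 0, 100), acceptor = c(100, 0, 100))
  expect_warning(e0 <- compute_fret(tr0), "non-positive total")
  expect_true(is.na(e0[2]))
  expect_equal(e0[c(1, 3)], c(0.5, 0.5))
})

test_that("FRET lifetime counts alive frames up to the first bleach", {
  expect_identical(fret_lifetime(rep(0.6, 80)), 80L)
  expect_identical(fret_lifetime(rep(0.05, 40)), 0L)
  set.seed(31)
  e <- c(runif(120, -0.05, 0.9), rep(NA, 30))
  expect_identical(fret_lifetime(e, 0.125),
                   as.integer(sum(e > 0.125, na.rm = TRUE)))
})

test_that("the six-trace defect fixture set is classified without mistakes", {
  fx <- defect_fixture_set()
  res <- select_traces(fx)
  rep <- res$report
  expect_identical(rep$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(length(res$traces), 1L)
  expect_identical(res$traces[[1]]$trace_id, "compliant")
  # each defective trace fails the criterion it was built to violate
  expect_false(rep$pass_single_step[rep$trace_id == "two_step"])
  expect_false(rep$pass_single_step[rep$trace_id == "no_bleach"])
  expect_false(rep$pass_lifetime[rep$trace_id == "short_lifetime"])
  expect_false(rep$pass_anticorrelation[rep$trace_id == "flat_uncorrelated"])
  expect_false(rep$pass_constant_total[rep$trace_id == "drifting"])
})

test_that("a compliant low-noise movie passes selection at >= 90%", {
  m <- state_model("X", "LBD-D677", "full_agonist", 0.5, 1)
  phys <- photophysics(noise_sd = 20, mean_donor_bleach_frames = 5000,
                       mean_acceptor_bleach_frames = 3000)
  sim <- simulate_movie(m, 200, phys, n_frames = 8000, seed = 17)
  res <- select_traces(sim$traces)
  expect_gte(mean(res$report$pass), 0.9)
})

test_that("genuine FRET dynamics anti-correlate the channels", {
  m <- state_model("X", "NTD-W56", "apo_like", c(0.3, 0.7), c(0.5, 0.5))
  phys <- photophysics(noise_sd = 20, mean_donor_bleach_frames = 1e6,
                       mean_acceptor_bleach_frames = 1e6)
  neg <- vapply(1:20, function(s) {
    path <- simulate_state_path(m, 400, seed = 100 + s)
    tr <- correct_trace(render_trace(path, m, phys, seed = 200 + s))
    cor(tr$donor, tr$acceptor) < 0
  }, TRUE)
  expect_true(all(neg))
})

test_that("loosening any single threshold never shrinks the passing set", {
  m <- condition_model("GluN2C", "NTD-W56", "apo_like")
  sim <- simulate_movie(m, 120, n_frames = 400, seed = 23)
  strict <- select_traces(sim$traces)$report
  loosened <- list(
    selection_criteria(min_fret_lifetime_frames = 20),
    selection_criteria(max_bleach_steps_per_channel = 3),
    selection_criteria(max_total_intensity_cv = 0.5),
    selection_criteria(max_channel_correlation = 0.5))
  for (crit in loosened) {
    loose <- select_traces(sim$traces, crit)$report
    expect_true(all(loose$pass[strict$pass]))
  }
})

test_that("empty input yields empty output and an empty report", {
  res <- select_traces(list())
  expect_identical(res$traces, list())
  expect_identical(nrow(res$report), 0L)
})
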