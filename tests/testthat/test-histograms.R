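test_that("constant-efficiency traces give delta histograms", {
  h <- trace_histogram(list(efficiency_trace(rep(0.35, 50))))
  expect_equal(sum(h$values), 1)
  expect_identical(sum(h$values > 0), 1L)
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  expect_lt(abs(centers[which(h$values > 0)] - 0.35), 0.02)

  h2 <- trace_histogram(list(efficiency_trace(rep(0.2, 50), "a"),
                             efficiency_trace(rep(0.8, 50), "b")))
  expect_equal(sort(h2$values[h2$values > 0]), c(0.5, 0.5))
})

test_that("histograms use the first window of valid frames and normalize", {
  e <- c(rep(NA, 5), rep(0.4, 60), rep(NA, 10))
  h <- trace_histogram(list(efficiency_trace(e)), window_frames = 50)
  expect_equal(sum(h$values), 1)
  expect_identical(h$n_traces, 1L)
  expect_equal(diff(h$bin_edges), rep(0.02, 60), tolerance = 1e-12)
  expect_warning(h0 <- trace_histogram(list()), "no valid frames")
  expect_identical(h0$n_traces, 0L)
  expect_true(all(h0$values == 0))
})

test_that("a simulated single-state movie peaks at the generating state mean", {
  m <- condition_model("GluN2A", "LBD-D677", "full_agonist")
  hists <- lapply(1:4, function(i) {
    sim <- simulate_movie(m, 150, n_frames = 600, seed = 18 + i)
    trace_histogram(select_traces(sim$traces)$traces)
  })
  ens <- average_histograms(hists)
  centers <- (ens$bin_edges[-1] + ens$bin_edges[-length(ens$bin_edges)]) / 2
  mode_center <- centers[which.max(ens$mean)]
  expect_lt(abs(mode_center - m$states$mean_fret[1]), 0.021)
})

test_that("ensemble averaging takes equal-weight means and SEM across movies", {
  h <- trace_histogram(list(efficiency_trace(rep(0.35, 50))))
  ens <- average_histograms(list(h, h, h, h))
  expect_equal(ens$mean, h$values)
  expect_true(all(ens$sem == 0))
  expect_identical(ens$n_movies, 4L)

  ha <- manual_histogram(c(1, rep(0, 59)))
  hb <- manual_histogram(c(0, 1, rep(0, 58)))
  ens2 <- average_histograms(list(ha, hb))
  expect_equal(ens2$mean[1:2], c(0.5, 0.5))
  expect_equal(sum(ens2$mean), 1, tolerance = 1e-9)

  # n = 4: SEM is the elementwise sample s.d. halved
  hs <- lapply(c(0.1, 0.2, 0.3, 0.4), function(v)
    manual_histogram(c(v, 1 - v, rep(0, 58))))
  ens4 <- average_histograms(hs)
  expect_equal(ens4$sem[1], sd(c(0.1, 0.2, 0.3, 0.4)) / 2)

  bad <- manual_histogram(rep(1 / 61, 61))
  bad$bin_edges <- seq(-0.1, 1.12, by = 0.02)
  expect_error(average_histograms(list(ha, bad)), "mismatched")
})

test_that("quartiles follow the strict cumulative-exceedance rule", {
  centers <- (fret_bin_edges()[-1] + fret_bin_edges()[-61]) / 2
  delta <- manual_histogram(replace(rep(0, 60), which.min(abs(centers - 0.35)), 1))
  q <- quartile_summary(list(delta))
  expect_equal(unname(q$mean), rep(centers[which.min(abs(centers - 0.35))], 3))

  # equal split over two bins: cumulative after the first is exactly 0.5,
  # which does not strictly exceed 0.5, so q50 moves to the second bin
  i1 <- 10L; i2 <- 30L
  split2 <- manual_histogram(replace(rep(0, 60), c(i1, i2), c(0.5, 0.5)))
  q2 <- quartile_summary(list(split2))$per_movie
  expect_equal(q2$q25, centers[i1])
  expect_equal(q2$q50, centers[i2])
  expect_equal(q2$q75, centers[i2])

  empty <- manual_histogram(rep(0, 60))
  expect_true(all(is.na(quartile_summary(list(empty))$mean)))
})

test_that("quartiles equal a brute-force cumulative scan on random histograms", {
  set.seed(41)
  centers <- (fret_bin_edges()[-1] + fret_bin_edges()[-61]) / 2
  brute <- function(v, p) {
    cum <- cumsum(v / sum(v))
    centers[which(cum > p)[1]]
  }
  for (i in 1:100) {
    v <- runif(60)^3
    v <- v / sum(v)
    h <- manual_histogram(v)
    q <- quartile_summary(list(h))$per_movie
    expect_identical(c(q$q25, q$q50, q$q75),
                     c(brute(v, 0.25), brute(v, 0.5), brute(v, 0.75)))
    expect_true(q$q25 <= q$q50 && q$q50 <= q$q75)
  }
})

test_that("translating efficiencies shifts quartiles by the bin-quantized offset", {
  set.seed(43)
  e <- runif(300, 0.2, 0.6)
  delta <- 0.04   # two bin widths
  q1 <- quartile_summary(list(trace_histogram(list(efficiency_trace(e)))))
  q2 <- quartile_summary(list(trace_histogram(list(efficiency_trace(e + delta)))))
  expect_equal(unname(q2$mean - q1$mean), rep(delta, 3), tolerance = 1e-9)
})
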