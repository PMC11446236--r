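test_that("condition model lookup returns published peak structure", {
  m <- condition_model("GluN2D", "NTD-W56", "apo_like")
  expect_equal(m$states$mean_fret, c(0.18, 0.60))
  expect_gt(m$occupancies[1], m$occupancies[2])   # splayed state dominates

  m2 <- condition_model("GluN2A", "LBD-D677", "full_agonist")
  expect_equal(m2$states$mean_fret[which.max(m2$occupancies)], 0.25)

  m3 <- condition_model("GluN2B", "NTD-W56", "glutamate_only")
  expect_equal(m3$states$mean_fret[which.max(m3$occupancies)], 0.30)

  expect_error(condition_model("GluN2Z", "NTD-W56", "apo_like"),
               "valid keys")
})

test_that("every packaged model satisfies its invariants", {
  keys <- condition_model_keys()
  for (i in seq_len(nrow(keys))) {
    m <- condition_model(keys$subtype[i], keys$probe_site[i],
                         keys$ligand_condition[i])
    expect_equal(sum(m$occupancies), 1, tolerance = 1e-9)
    expect_true(all(m$states$mean_fret >= 0 & m$states$mean_fret <= 1))
    expect_true(all(m$states$width > 0))
    expect_true(all(m$states$mean_dwell_frames >= 1))
  }
})

test_that("labeling stoichiometry has the two-site probabilities", {
  # analytic: two independent sites, P(DA) = 2 * 1/2 * 1/2 = 1/2
  draws <- assign_label_stoichiometry(10000, seed = 11)
  expect_equal(length(draws), 10000L)
  p_da <- mean(draws == "DA")
  expect_lt(abs(p_da - 0.5), 3 * sqrt(0.25 / 10000))
  # DD and AA each ~1/4
  expect_lt(abs(mean(draws == "DD") - 0.25), 4 * sqrt(0.1875 / 10000))
  expect_identical(draws, assign_label_stoichiometry(10000, seed = 11))
  expect_setequal(unique(draws), c("DA", "DD", "AA"))
})

test_that("single-state models give constant state paths", {
  m <- state_model("X", "LBD-D677", "full_agonist", 0.5, 1)
  expect_identical(simulate_state_path(m, 500, seed = 1), rep(1L, 500))
})

test_that("symmetric two-state occupancy is recovered over long paths", {
  m <- state_model("X", "NTD-W56", "apo_like", c(0.2, 0.7), c(0.5, 0.5))
  path <- simulate_state_path(m, 1e5, seed = 3)
  # crude i.i.d. bound inflated for autocorrelation (dwell ~20 frames)
  expect_lt(abs(mean(path == 1L) - 0.5), 3 * sqrt(0.25 * 40 / 1e5))
})

test_that("empirical transitions match the chain whose stationary law is the occupancies", {
  m <- state_model("X", "NTD-W56", "apo_like", c(0.2, 0.5, 0.8),
                   c(0.5, 0.3, 0.2), mean_dwell_frames = c(10, 20, 40))
  P <- smfretr:::state_transition_matrix(m)
  # power-iteration oracle for the stationary vector
  v <- rep(1 / 3, 3)
  for (i in 1:10000) v <- as.numeric(v %*% P)
  expect_equal(v, m$occupancies, tolerance = 1e-9)

  path <- simulate_state_path(m, 2e5, seed = 5)
  emp_freq <- tabulate(path, 3) / length(path)
  expect_equal(emp_freq, m$occupancies, tolerance = 0.04)
  # empirical one-step transition frequencies against the constructed matrix
  emp_P <- prop.table(table(factor(head(path, -1), 1:3),
                            factor(path[-1], 1:3)), 1)
  expect_lt(max(abs(emp_P - P)), 0.02)
})

test_that("stationary occupancy recovery holds across generated models", {
  set.seed(99)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    occ <- as.numeric(prop.table(runif(k, 0.2, 1)))
    m <- state_model("X", "NTD-W56", "apo_like",
                     mean_fret = sort(runif(k)), occupancies = occ,
                     mean_dwell_frames = sample(5:40, k, replace = TRUE))
    path <- simulate_state_path(m, 1e5)
    emp <- tabulate(path, k) / length(path)
    # 3 binomial s.d. inflated by the dwell-time autocorrelation factor
    tol <- 3 * sqrt(pmax(occ * (1 - occ), 0.01) * 2 * 40 / 1e5)
    expect_true(all(abs(emp - occ) < tol))
  }
})

test_that("noise-free rendering is exactly inverted by the correction pipeline", {
  m <- state_model("X", "LBD-D677", "full_agonist", 0.6, 1)
  phys <- photophysics(noise_sd = 0, background = 0,
                       mean_donor_bleach_frames = 1e6,
                       mean_acceptor_bleach_frames = 1e6)
  path <- simulate_state_path(m, 200, seed = 2)
  tr <- render_trace(path, m, phys, seed = 4)
  e <- compute_fret(correct_trace(tr),
                    tr$true_bleach_frames[["donor"]],
                    tr$true_bleach_frames[["acceptor"]])
  pre <- seq_len(min(tr$true_bleach_frames, 200))
  expect_lt(max(abs(e[pre] - tr$true_efficiency[pre])), 1e-9)
})

test_that("rendered phases show dequenching and darkness", {
  m <- state_model("X", "LBD-D677", "full_agonist", 0.6, 1)
  phys <- photophysics(noise_sd = 0, background = 0,
                       mean_donor_bleach_frames = 120,
                       mean_acceptor_bleach_frames = 30)
  # draw until acceptor bleaches well before donor within the trace
  for (s in 1:200) {
    tr <- render_trace(rep(1L, 200), m, phys, seed = s)
    ab <- tr$true_bleach_frames[["acceptor"]]
    db <- tr$true_bleach_frames[["donor"]]
    if (ab < db - 5 && db < 190) break
  }
  frame0 <- 0:199
  deq <- frame0 >= ab & frame0 < db
  expect_true(all(abs(tr$donor[deq] - phys$total_intensity) < 1e-9))
  dark <- frame0 >= db
  expect_true(all(abs(tr$donor[dark]) < 1e-9))
  expect_true(all(abs(tr$acceptor[dark]) < 1e-9))
  # acceptor during dequench carries only donor bleed-through
  expect_true(all(abs(tr$acceptor[deq] -
                        0.15 * phys$total_intensity / 1.2) < 1e-9))
})

test_that("movies conserve stoichiometry counts and are seed-deterministic", {
  m <- condition_model("GluN2A", "LBD-D677", "full_agonist")
  sim <- simulate_movie(m, 1000, n_frames = 10, seed = 21)
  man <- sim$manifest
  expect_identical(man$n_DA + man$n_DD + man$n_AA, 1000L)
  expect_lt(abs(man$n_DA - 500), 3 * sqrt(1000 * 0.25))
  expect_identical(length(sim$traces), man$n_DA)

  sim2 <- simulate_movie(m, 1000, n_frames = 10, seed = 21)
  expect_identical(sim, sim2)
  expect_error(simulate_movie(m, 0), ">= 1")
})
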