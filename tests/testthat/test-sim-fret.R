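test_that("single-state trace with E = 0.5 and no noise has equal channels", {
  cfg <- fret_sim_config(state_means = 0.5, rate_matrix = matrix(0, 1, 1),
                         noise_sd = 0, bleach_rate = 0,
                         n_traces = 2, n_frames_max = 30, seed = 1)
  sim <- simulate_fret_traces(cfg)
  for (tr in sim$traces)
    expect_equal(tr$donor, tr$acceptor, tolerance = 1e-12)
})

test_that("zero transition rates freeze each trace in its initial state", {
  cfg <- fret_sim_config(state_means = c(0.3, 0.7),
                         rate_matrix = matrix(0, 2, 2),
                         noise_sd = 0, bleach_rate = 0,
                         n_traces = 10, n_frames_max = 50, seed = 2)
  sim <- simulate_fret_traces(cfg)
  for (tr in sim$traces)
    expect_length(unique(tr$state_id), 1L)
})

test_that("per-state mean FRET matches the ground-truth state path", {
  sim <- small_fret_sim(n_traces = 200, n_frames = 500, seed = 3)
  # oracle: average ideal efficiency over frames with a known state label,
  # restricted to frames fully inside one state (no mid-frame transition)
  e_by_state <- vapply(1:4, function(s) {
    vals <- unlist(lapply(sim$traces, function(tr) {
      pure <- tr$state_id == s & !tr$bleached &
        abs(tr$true_E - four_state_means[s]) < 1e-9
      tr$acceptor[pure] / sim$config$total_intensity
    }))
    mean(vals)
  }, numeric(1))
  expect_equal(e_by_state, four_state_means, tolerance = 0.01 /
                 max(four_state_means))
})

test_that("transition counts are consistent with the rate matrix", {
  k <- equilibrium_rate_matrix(c(0.5, 0.5), k_ex = 0.4)
  cfg <- fret_sim_config(state_means = c(0.3, 0.7), rate_matrix = k,
                         noise_sd = 0, bleach_rate = 0,
                         n_traces = 30, n_frames_max = 400, seed = 4)
  sim <- simulate_fret_traces(cfg)
  trans <- sum(vapply(sim$traces,
                      function(tr) sum(diff(tr$state_id) != 0L),
                      numeric(1)))
  n_frames <- 30 * 400
  # per-frame switch probability ~ k_ij * dt = 0.2 * 0.1
  p <- 0.2 * 0.1
  expect_lt(abs(trans - n_frames * p), 4 * sqrt(n_frames * p * (1 - p)))
})

test_that("generators are reproducible under a fixed seed", {
  a <- small_fret_sim(n_traces = 3, n_frames = 50, seed = 7)
  b <- small_fret_sim(n_traces = 3, n_frames = 50, seed = 7)
  expect_identical(a$traces, b$traces)
})

test_that("invalid configurations are rejected", {
  expect_error(fret_sim_config(state_means = c(0.5, 0.4)))
  expect_error(fret_sim_config(state_means = c(0.2, 1.2)))
  bad <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
  bad[1, 2] <- -1  # negative off-diagonal
  expect_error(fret_sim_config(state_means = c(0.3, 0.7),
                               rate_matrix = bad),
               "off-diagonals")
  nonconservative <- matrix(c(-1, 2, 1, -1), 2, 2, byrow = TRUE)
  expect_error(fret_sim_config(state_means = c(0.3, 0.7),
                               rate_matrix = nonconservative),
               "sum to zero")
})

test_that("equilibrium rate matrix has the requested stationary law", {
  pi0 <- c(0.4, 0.3, 0.2, 0.1)
  k <- equilibrium_rate_matrix(pi0, k_ex = 1)
  expect_equal(rowSums(k), rep(0, 4), tolerance = 1e-12)
  expect_equal(as.numeric(pi0 %*% k), rep(0, 4), tolerance = 1e-12)
})
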