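test_that("frames from one Gaussian collapse to a single dominant component", {
  set.seed(20)
  ys <- replicate(30, stats::rnorm(200, 0.5, 0.05), simplify = FALSE)
  # two candidate components: all mass must land on the one at 0.5
  hf <- fit_fret_histogram(ys, c(0.2, 0.5), seed = 1)
  expect_gt(hf$populations[["0.50"]], 98)
})

test_that("equal draws from two separated Gaussians split 50/50", {
  set.seed(21)
  ys <- replicate(40, {
    mu <- sample(c(0.3, 0.7), 1)
    stats::rnorm(150, mu, 0.05)
  }, simplify = FALSE)
  # force near-equal molecule counts by drawing many molecules
  hf <- fit_fret_histogram(ys, c(0.3, 0.7), seed = 2)
  expect_equal(unname(hf$populations[["0.30"]]),
               100 * mean(vapply(ys, function(y) mean(y) < 0.5,
                                 logical(1))),
               tolerance = 2.5)
})

test_that("four-state occupancies are recovered within three points", {
  occ <- c(0.267, 0.349, 0.246, 0.139)
  occ <- occ / sum(occ)
  sim <- simulate_fret_traces(fret_sim_config(
    occupancies = occ, k_ex = 0.5, n_traces = 120, n_frames_max = 400,
    seed = 22))
  fts <- valid_fret_traces(sim)
  hf <- fit_fret_histogram(fts, four_state_means, seed = 3)
  # oracle: the occupancy realised by the ground-truth state path
  realised <- prop.table(table(factor(unlist(lapply(
    sim$traces, function(tr) tr$state_id[!tr$bleached])), levels = 1:4)))
  expect_true(all(abs(hf$populations - 100 * as.numeric(realised)) < 1.5))
  expect_true(all(abs(hf$populations - 100 * occ) < 3))
})

test_that("populations sum to one hundred within half a point", {
  sim <- small_fret_sim(n_traces = 40, n_frames = 300, seed = 23)
  hf <- fit_fret_histogram(valid_fret_traces(sim), four_state_means,
                           seed = 4)
  expect_equal(sum(hf$populations), 100, tolerance = 0.5 / 100)
})

test_that("per-bin standard errors are non-negative and populated", {
  sim <- small_fret_sim(n_traces = 40, n_frames = 300, seed = 24)
  hf <- fit_fret_histogram(valid_fret_traces(sim), four_state_means,
                           n_boot = 30, seed = 5)
  expect_true(all(hf$se >= 0))
  expect_gt(max(hf$se), 0)
})

test_that("underdetermined histogram fits are refused", {
  ys <- list(stats::rnorm(30, 0.5, 0.05))
  expect_error(fit_fret_histogram(ys, four_state_means), "refused")
})
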