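test_that("noiseless two-level square wave gives exactly two states", {
  y <- rep(rep(c(0.2, 0.8), each = 25), 4)
  st <- stasi(y)
  expect_identical(st$n_states, 2L)
  expect_equal(st$means, c(0.2, 0.8))
})

test_that("a constant noisy trace yields a single state", {
  set.seed(10)
  st <- stasi(stats::rnorm(400, 0.5, 0.05))
  expect_identical(st$n_states, 1L)
  expect_equal(st$means, 0.5, tolerance = 0.02)
})

test_that("two well-separated noisy levels are recovered", {
  set.seed(11)
  ys <- replicate(10, {
    lev <- rep(sample(c(0.25, 0.75), 8, replace = TRUE), each = 40)
    lev + stats::rnorm(length(lev), 0, 0.05)
  }, simplify = FALSE)
  st <- stasi(ys)
  expect_identical(st$n_states, 2L)
  expect_equal(st$means, c(0.25, 0.75), tolerance = 0.02)
})

test_that("four-state synthetic data is recovered with accurate means", {
  sim <- small_fret_sim(n_traces = 120, n_frames = 400, seed = 12)
  fts <- valid_fret_traces(sim)
  st <- stasi(fts)
  expect_identical(st$n_states, 4L)
  expect_equal(st$means, four_state_means, tolerance = 0.02 / 0.78)
  # oracle: means over the ground-truth state labels
  truth_means <- vapply(1:4, function(s) {
    mean(unlist(lapply(sim$traces, function(tr) {
      keep <- tr$state_id == s & !tr$bleached
      (tr$acceptor[keep]) / sim$config$total_intensity
    })))
  }, numeric(1))
  expect_equal(st$means, truth_means, tolerance = 0.02 / 0.78)
})

test_that("MDL is unimodal around the selected state count", {
  sim <- small_fret_sim(n_traces = 120, n_frames = 400, seed = 12)
  st <- stasi(valid_fret_traces(sim))
  i <- which(st$mdl$m == st$n_states)
  before <- st$mdl$mdl[seq_len(i)]
  after <- st$mdl$mdl[i:nrow(st$mdl)]
  expect_true(all(diff(before) <= 0))
  expect_true(all(diff(after) >= 0))
})

test_that("noise sd estimate is close to the frame-level truth", {
  set.seed(13)
  y <- rep(c(0.3, 0.7), each = 200) + stats::rnorm(400, 0, 0.04)
  st <- stasi(y)
  expect_equal(st$sigma, 0.04, tolerance = 0.2)
})

test_that("degenerate noiseless input falls back to level counting", {
  y <- c(rep(0.1, 20), rep(0.5, 20), rep(0.9, 20))
  st <- stasi(y)
  expect_identical(st$n_states, 3L)
  expect_equal(st$means, c(0.1, 0.5, 0.9))
})

test_that("assignments reference existing states and cover all frames", {
  sim <- small_fret_sim(n_traces = 30, n_frames = 200, seed = 14)
  fts <- valid_fret_traces(sim)
  st <- stasi(fts)
  expect_length(st$assignments, length(fts))
  for (i in seq_along(fts)) {
    a <- st$assignments[[i]]
    expect_length(a, fts[[i]]$n_valid)
    expect_true(all(a >= 1L & a <= st$n_states))
  }
})
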