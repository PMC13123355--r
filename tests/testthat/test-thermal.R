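test_that("melt generator hits the midpoint and approaches a step", {
  cfg <- melt_sim_config(tm = 55, noise_sd = 0)
  cv <- simulate_melt_curve(cfg)
  f_mid <- (cfg$f_min + cfg$f_max) / 2
  expect_equal(stats::approx(cv$temperature, cv$fluorescence, 55)$y,
               f_mid, tolerance = 1e-9)
  # slope -> 0+ approaches a step at tm
  steep <- simulate_melt_curve(melt_sim_config(tm = 55, slope = 1e-3,
                                               noise_sd = 0))
  below <- steep$temperature < 54.5
  above <- steep$temperature > 55.5
  expect_lt(max(abs(steep$fluorescence[below] - cfg$f_min)), 1e-9)
  expect_lt(max(abs(steep$fluorescence[above] - cfg$f_max)), 1e-9)
})

test_that("noiseless fits return the generating parameters exactly", {
  cv <- simulate_melt_curve(melt_sim_config(tm = 55, noise_sd = 0))
  fit <- fit_boltzmann(cv)
  expect_equal(fit$tm, 55, tolerance = 1e-6)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  # fitted midpoint identity
  expect_equal(predict(fit, fit$tm), (fit$f_min + fit$f_max) / 2,
               tolerance = 1e-6)
})

test_that("fits are invariant to affine rescaling of the signal", {
  cv <- simulate_melt_curve(melt_sim_config(tm = 59.7, seed = 70))
  f1 <- fit_boltzmann(cv)
  cv2 <- cv
  cv2$fluorescence <- 3.2 * cv$fluorescence + 17
  f2 <- fit_boltzmann(cv2)
  expect_equal(f2$tm, f1$tm, tolerance = 1e-6)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
})

test_that("descending curves are detected and fitted with swapped plateaus", {
  cv <- simulate_melt_curve(melt_sim_config(tm = 55, seed = 71))
  cv$fluorescence <- 1.1 - cv$fluorescence
  fit <- fit_boltzmann(cv)
  expect_identical(fit$direction, "descending")
  expect_equal(fit$tm, 55, tolerance = 0.3 / 55)
})

test_that("flat curves raise a no-transition error", {
  set.seed(72)
  cv <- data.frame(temperature = seq(20, 90, by = 0.5))
  cv$fluorescence <- 0.5 + stats::rnorm(nrow(cv), 0, 0.01)
  expect_error(fit_boltzmann(cv), "transition")
})

test_that("recovery is unbiased within a tenth of a degree", {
  tm_hat <- vapply(1:50, function(s)
    fit_boltzmann(simulate_melt_curve(melt_sim_config(tm = 55,
                                                      seed = s)))$tm,
    numeric(1))
  expect_lt(abs(mean(tm_hat) - 55), 0.1)
  expect_true(all(abs(tm_hat - 55) < 0.3))
})

test_that("melting-temperature shifts subtract with propagated error", {
  fa <- fit_boltzmann(simulate_melt_curve(melt_sim_config(tm = 55,
                                                          seed = 73)))
  fb <- fit_boltzmann(simulate_melt_curve(melt_sim_config(tm = 59.7,
                                                          seed = 74)))
  d <- delta_tm(fa, fb)
  expect_equal(d$delta_tm, 4.7, tolerance = 0.3 / 4.7)
  expect_equal(delta_tm(fb, fa)$delta_tm, -d$delta_tm)
  expect_equal(delta_tm(fa, fa)$delta_tm, 0)
  expect_gt(d$se, 0)
})
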