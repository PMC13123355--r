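test_that("noiseless single-component spectrum conserves the area", {
  cfg <- qens_sim_config(noise_rel = 0, A_broad = 0, bg_offset = 0,
                         bg_slope = 0, temperatures = 300, q_values = 1)
  sp <- simulate_qens(cfg)$spectra[[1]]
  # the Lorentzian loses a known tail fraction outside +/-100 ueV
  g <- simulate_qens(cfg)$truth$gamma_narrow
  coverage <- 2 / pi * atan(100 / g)
  expect_equal(pracma::trapz(sp$energy, sp$intensity),
               cfg$A_narrow * coverage, tolerance = 5e-3)
})

test_that("narrow widths follow the exact Q^2 law in the generator", {
  cfg <- qens_sim_config(temperatures = 300, q_values = c(1, sqrt(2)),
                         noise_rel = 0)
  tr <- simulate_qens(cfg)$truth
  expect_equal(tr$gamma_narrow[2] / tr$gamma_narrow[1], 2, tolerance = 1e-9)
})

test_that("generated log-rates are collinear in 1/T before noise", {
  cfg <- qens_sim_config(noise_rel = 0)
  tr <- simulate_qens(cfg)$truth
  r <- unique(tr[, c("temperature", "rate")])
  fit <- stats::lm(log(rate) ~ I(1 / temperature), data = r)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  expect_equal(-stats::coef(fit)[[2]] * 8.314 / 1000, 8.2,
               tolerance = 1e-9)
})

test_that("noiseless spectra are symmetric in energy", {
  cfg <- qens_sim_config(noise_rel = 0, bg_slope = 0,
                         temperatures = 300, q_values = 1)
  sp <- simulate_qens(cfg)$spectra[[1]]
  expect_equal(sp$intensity, rev(sp$intensity), tolerance = 1e-10)
})

test_that("too-coarse energy grids are rejected", {
  expect_error(qens_sim_config(energy_grid = seq(-100, 100, by = 1)),
               "coarse")
})

test_that("noiseless fits recover the generating widths almost exactly", {
  cfg <- qens_sim_config(noise_rel = 0, temperatures = 300, q_values = 1.1)
  sim <- simulate_qens(cfg)
  fit <- fit_qens_spectrum(sim$spectra[[1]])
  expect_equal(fit$gamma_narrow, sim$truth$gamma_narrow, tolerance = 0.01)
  expect_equal(fit$gamma_broad, sim$truth$gamma_broad, tolerance = 0.01)
  # residuals essentially at machine/fit precision
  expect_lt(max(abs(fit$fitted - sim$spectra[[1]]$intensity)),
            1e-6 * max(sim$spectra[[1]]$intensity))
})

test_that("both widths are recovered within five percent at one percent noise", {
  cfg <- qens_sim_config(noise_rel = 0.01, temperatures = 300,
                         q_values = 1.3, seed = 30)
  sim <- simulate_qens(cfg)
  fit <- fit_qens_spectrum(sim$spectra[[1]])
  expect_equal(fit$gamma_narrow, sim$truth$gamma_narrow, tolerance = 0.05)
  expect_equal(fit$gamma_broad, sim$truth$gamma_broad, tolerance = 0.05)
})

test_that("fits are invariant to uniform intensity rescaling", {
  cfg <- qens_sim_config(noise_rel = 0.01, temperatures = 300,
                         q_values = 1, seed = 31)
  sp <- simulate_qens(cfg)$spectra[[1]]
  sp10 <- qens_spectrum(sp$energy, 10 * sp$intensity, 10 * sp$sigma,
                        sp$resolution, sp$q, sp$temperature)
  f1 <- fit_qens_spectrum(sp)
  f2 <- fit_qens_spectrum(sp10)
  expect_equal(f2$gamma_narrow, f1$gamma_narrow, tolerance = 1e-6)
  expect_equal(f2$gamma_broad, f1$gamma_broad, tolerance = 1e-6)
  expect_equal(f2$A_narrow, 10 * f1$A_narrow, tolerance = 1e-6)
})

test_that("diffusivity fit matches exact and noisy Q^2 data", {
  q <- c(0.7, 0.9, 1.1, 1.3, 1.5)
  expect_equal(suppressWarnings(fit_global_diffusion(2 * q^2, q))$D, 2,
               tolerance = 1e-12)
  set.seed(32)
  g <- 1.5 * q^2 * (1 + stats::rnorm(5, 0, 0.03))
  d <- fit_global_diffusion(g, q, se = 0.03 * 1.5 * q^2)
  expect_equal(d$D, 1.5, tolerance = 0.05)
  # linearity: doubling the widths doubles D
  expect_equal(suppressWarnings(fit_global_diffusion(4 * q^2, q))$D,
               2 * suppressWarnings(fit_global_diffusion(2 * q^2, q))$D,
               tolerance = 1e-12)
  expect_error(fit_global_diffusion(-2 * q^2, q), "negative|unphysical")
})

test_that("power-law fit is exact on exact data and converts to tau", {
  q <- c(0.7, 0.9, 1.1, 1.3, 1.5)
  f <- suppressWarnings(fit_internal_dynamics(12 * q^1.8, q))
  expect_equal(f$rate, 12, tolerance = 1e-9)
  expect_equal(f$alpha, 1.8, tolerance = 1e-9)
  expect_equal(f$tau0_ps, 658.2 / 12, tolerance = 1e-9)
  expect_equal(hwhm_to_tau(12), 54.85, tolerance = 1e-3)
  # Q-independent widths: rate equals the common width, alpha ~ 0
  f0 <- suppressWarnings(fit_internal_dynamics(rep(5, 5), q))
  expect_equal(f0$rate, 5, tolerance = 1e-9)
  expect_equal(f0$alpha, 0, tolerance = 1e-9)
  expect_error(fit_internal_dynamics(c(-1, 2, 3), q[1:3]))
})

test_that("Arrhenius fit matches the two-point closed form", {
  ea <- suppressWarnings(arrhenius_fit(c(1, 2), c(280, 310)))$Ea_kJ_mol
  closed <- 8.314 * log(2) / (1 / 280 - 1 / 310) / 1000
  expect_equal(ea, closed, tolerance = 1e-9)
  expect_equal(closed, 16.7, tolerance = 0.1 / 16.7)
  expect_equal(suppressWarnings(arrhenius_fit(
    rep(3, 4), c(280, 290, 300, 310)))$Ea_kJ_mol, 0, tolerance = 1e-9)
  expect_error(arrhenius_fit(c(1, -2), c(280, 310)), "positive")
})

test_that("activation energy is recovered from noisy synthetic rates", {
  # closed-form generation at the configured activation energy, many
  # replicates: the estimator must be unbiased and inside the band
  set.seed(33)
  temps <- c(280, 290, 300, 310)
  truth <- 8.2
  ea_hat <- replicate(100, {
    r <- 288 * exp(-truth * 1000 / (8.314 * temps)) *
      (1 + stats::rnorm(4, 0, 0.03))
    arrhenius_fit(r, temps)$Ea_kJ_mol
  })
  # one rate per temperature: the estimator must be unbiased with a
  # spread consistent with error propagation (~1 kJ/mol at 3% noise)
  expect_lt(abs(mean(ea_hat) - truth), 0.35)
  expect_lt(stats::sd(ea_hat), 1.6)
})

test_that("narrow width over Q^2 is constant when data obey the law", {
  cfg <- qens_sim_config(noise_rel = 0.01, temperatures = 300, seed = 34)
  sim <- simulate_qens(cfg)
  fits <- lapply(sim$spectra, fit_qens_spectrum)
  ratio <- vapply(fits, function(f) f$gamma_narrow / f$q^2, numeric(1))
  expect_lt(stats::sd(ratio) / mean(ratio), 0.1)
})

test_that("buffer subtraction removes an added buffer signal", {
  cfg <- qens_sim_config(noise_rel = 0, temperatures = 300, q_values = 1)
  sp <- simulate_qens(cfg)$spectra[[1]]
  buf <- 0.003 + 2e-5 * abs(sp$energy)
  spb <- qens_spectrum(sp$energy, sp$intensity + buf, sp$sigma,
                       sp$resolution, sp$q, sp$temperature)
  f <- fit_qens_spectrum(spb, buffer = buf)
  expect_equal(f$gamma_narrow, fit_qens_spectrum(sp)$gamma_narrow,
               tolerance = 1e-6)
})
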