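test_that("rectangular toy spectra reproduce the closed-form overlap", {
  r <- forster_radius(rect_donor(), rect_acceptor(), quantum_yield = 0.3,
                      kappa2 = 2 / 3, refractive_index = 1.4)
  # hand integral: J = 1e5 * mean(lambda^4 over 550..600) over the
  # donor-normalised rectangle
  lam <- seq(550, 600, by = 0.5)
  J_exact <- 1e5 * pracma::trapz(lam, lam^4) / (600 - 550)
  expect_equal(r$J, J_exact, tolerance = 1e-3)
  R0_exact <- 0.211 * ((2 / 3) * 1.4^-4 * 0.3 * J_exact)^(1 / 6)
  expect_equal(r$R0, R0_exact, tolerance = 1e-3)
})

test_that("zero quantum yield gives a zero radius", {
  r <- forster_radius(rect_donor(), rect_acceptor(), quantum_yield = 0)
  expect_equal(r$R0, 0)
})

test_that("doubling the extinction scales R0 by 2^(1/6)", {
  r1 <- forster_radius(rect_donor(), rect_acceptor(1e5), quantum_yield = 0.3)
  r2 <- forster_radius(rect_donor(), rect_acceptor(2e5), quantum_yield = 0.3)
  expect_equal(r2$R0 / r1$R0, 2^(1 / 6), tolerance = 1e-9)
})

test_that("non-overlapping spectra are rejected", {
  don <- data.frame(lambda = 500:540, intensity = 1)
  acc <- data.frame(lambda = 600:650, epsilon = 1e5)
  expect_error(forster_radius(don, acc, quantum_yield = 0.3), "overlap")
})

test_that("distance relation has the R0 anchor and exact inverse", {
  expect_equal(fret_to_distance(0.5, 54.8), 54.8)
  expect_equal(fret_to_distance(0.49, 54.8), 55.2, tolerance = 0.1 / 55)
  # round trip E -> r -> E
  for (e in c(0.1, 0.33, 0.49, 0.63, 0.78, 0.9)) {
    r <- fret_to_distance(e, 54.8)
    expect_equal(1 / (1 + (r / 54.8)^6), e, tolerance = 1e-12)
  }
  expect_error(fret_to_distance(0, 54.8))
  expect_error(fret_to_distance(1, 54.8))
})

test_that("distance is strictly decreasing in efficiency", {
  e <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(fret_to_distance(e, 54.8)) < 0))
})

test_that("displacement is antisymmetric and zero at equal states", {
  expect_equal(fret_displacement(0.49, 0.78, 54.8),
               -fret_displacement(0.78, 0.49, 54.8))
  expect_equal(fret_displacement(0.6, 0.6, 54.8), 0)
})
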