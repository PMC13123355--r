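test_that("Debye curve closed forms hold for one and two beads", {
  one <- bead_model(matrix(0, 1, 3))
  cv <- debye_curve(one, c(0.01, 0.1, 0.3))
  expect_equal(cv$intensity, rep(1, 3), tolerance = 1e-12)

  d <- 30
  two <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  q <- c(0.02, 0.07, 0.15)
  cv2 <- debye_curve(two, q)
  expect_equal(cv2$intensity, 2 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-12)
  expect_equal(attr(cv2, "I0"), 4)
})

test_that("filled-sphere model reproduces the analytic radius of gyration", {
  r_sph <- 61.5
  sph <- sphere_bead_model(r_sph)
  cv <- debye_curve(sph, default_q_grid)
  gf <- guinier_fit(cv)
  expect_equal(gf$Rg, r_sph * sqrt(3 / 5), tolerance = 0.03)
})

test_that("Debye curve decays monotonically over the Guinier region", {
  sph <- sphere_bead_model(40)
  cv <- debye_curve(sph, default_q_grid)
  rg <- bead_rg(sph)
  guinier <- cv$q * rg <= 1.3
  expect_true(all(diff(cv$intensity[guinier]) < 0))
})

test_that("Guinier fit is exact on exact Guinier-law data", {
  rg <- 40
  q <- seq(0.004, 0.08, by = 0.001)
  i <- 1000 * exp(-(rg^2 / 3) * q^2)
  gf <- guinier_fit(scattering_curve(q, i, 0.01 * i))
  expect_equal(gf$Rg, rg, tolerance = 1e-6)
  expect_equal(gf$I0, 1000, tolerance = 1e-6)
  expect_lte(gf$qrg_max, 1.3 + 0.05)
  # scale invariance
  gf10 <- guinier_fit(scattering_curve(q, 10 * i, 0.1 * i))
  expect_equal(gf10$I0, 10 * gf$I0, tolerance = 1e-9)
  expect_equal(gf10$Rg, gf$Rg, tolerance = 1e-12)
})

test_that("mixtures reproduce inputs in the degenerate cases", {
  basis <- oligomer_basis()
  m1 <- simulate_sas_mixture(basis[1], 1, noise_rel = 0)
  expect_equal(m1$intensity, basis[[1]]$intensity, tolerance = 1e-12)
  m2 <- simulate_sas_mixture(list(basis[[2]], basis[[2]]), c(0.5, 0.5),
                             noise_rel = 0)
  expect_equal(m2$intensity, basis[[2]]$intensity, tolerance = 1e-12)
  # mismatched grids rejected
  short <- scattering_curve(basis[[1]]$q[-1], basis[[1]]$intensity[-1])
  expect_error(simulate_sas_mixture(list(basis[[1]], short), c(1, 1)),
               "q grid")
})

test_that("NNLS recovers known mixture weights", {
  basis <- oligomer_basis()
  # basis = target alone
  nn1 <- nnls_weights(basis[1], basis[[1]])
  expect_equal(unname(nn1$weights), 1, tolerance = 1e-9)
  # noiseless 50/50 of two distinct members
  mix <- simulate_sas_mixture(basis[c(1, 4)], c(0.5, 0.5), noise_rel = 0)
  nn2 <- nnls_weights(basis[c(1, 4)], mix)
  expect_equal(unname(nn2$weights), c(0.5, 0.5), tolerance = 1e-6)
  # four-component mixture with noise: oracle = NNLS on the true basis
  w_true <- c(0.821, 0.037, 0.037, 0.105)
  mix4 <- simulate_sas_mixture(basis, w_true, noise_rel = 0.01, seed = 40)
  nn4 <- nnls_weights(basis, mix4)
  expect_equal(unname(nn4$weights), w_true, tolerance = 0.03 / 0.037)
  expect_true(all(abs(nn4$weights - w_true) < 0.03))
  # wrong basis is detected by a large misfit
  wrong <- lapply(decoy_bead_models(3, seed = 41), debye_curve,
                  q_values = default_q_grid)
  expect_gt(nnls_weights(wrong, mix4)$chi2_red, 10)
})

test_that("weighted residual is orthogonal to active basis members", {
  basis <- oligomer_basis()
  mix <- simulate_sas_mixture(basis, c(0.6, 0.2, 0.1, 0.1),
                              noise_rel = 0.01, seed = 42)
  nn <- nnls_weights(basis, mix)
  res <- (mix$intensity - nn$fitted) / mix$sigma
  for (k in which(nn$weights > 1e-8)) {
    a_k <- basis[[k]]$intensity / mix$sigma
    cosine <- sum(res * a_k) / sqrt(sum(res^2) * sum(a_k^2))
    expect_lt(abs(cosine), 1e-6)
  }
})

test_that("P(r) locates the pair separation of a two-bead model", {
  d <- 45
  two <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  cv <- debye_curve(two, seq(0.01, 0.6, by = 0.004))
  pr <- suppressWarnings(pr_transform(cv, dmax = 70, n_r = 71))
  away <- pr$r > 10
  mode_r <- pr$r[away][which.max(pr$P[away])]
  expect_equal(mode_r, d, tolerance = 5 / 45)
})

test_that("P(r) moments reproduce the sphere radius of gyration", {
  sph <- sphere_bead_model(50)
  cv <- debye_curve(sph, default_q_grid)
  pr <- pr_transform(cv, dmax = 105)
  expect_equal(pr$Rg, 50 * sqrt(3 / 5), tolerance = 0.03)
  expect_equal(pr$P[1], 0)
  expect_equal(pr$P[length(pr$P)], 0)
})

test_that("data misfit grows monotonically with the regularization weight", {
  sph <- sphere_bead_model(40)
  cv <- debye_curve(sph, default_q_grid)
  lams <- 10^seq(-3, 3, by = 1.5)
  chis <- vapply(lams, function(l)
    pr_transform(cv, dmax = 85, reg_weight = l)$chi2_red, numeric(1))
  expect_true(all(diff(chis) >= -1e-8))
})

test_that("Guinier and P(r) size estimates agree on a smooth single species", {
  sph <- sphere_bead_model(55)
  cv <- debye_curve(sph, default_q_grid)
  rg_g <- guinier_fit(cv)$Rg
  rg_p <- pr_transform(cv, dmax = 115)$Rg
  expect_equal(rg_p, rg_g, tolerance = 0.03)
})
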