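test_that("a target equal to one pool member yields a size-1 solution", {
  basis <- oligomer_basis()
  pool <- c(basis, lapply(decoy_bead_models(4, seed = 50), debye_curve,
                          q_values = default_q_grid))
  tgt <- scattering_curve(basis[[1]]$q, basis[[1]]$intensity,
                          0.01 * basis[[1]]$intensity)
  ens <- ga_select(pool, tgt, n_max = 3, seed = 51)
  expect_identical(ens$size, 1L)
  expect_identical(unname(ens$members), "monomer")
  expect_equal(unname(ens$weights), 1, tolerance = 1e-9)
})

test_that("best fitness never degrades across generations", {
  basis <- oligomer_basis()
  pool <- c(basis, lapply(decoy_bead_models(8, seed = 52), debye_curve,
                          q_values = default_q_grid))
  tgt <- simulate_sas_mixture(basis, c(0.6, 0.1, 0.1, 0.2),
                              noise_rel = 0.01, seed = 53)
  ens <- ga_select(pool, tgt, seed = 54)
  expect_true(all(diff(ens$history) <= 0))
})

test_that("GA recovers the true components among decoys", {
  basis <- oligomer_basis()
  w_true <- c(monomer = 0.821, dimer = 0.037, trimer = 0.037,
              tetramer = 0.105)
  tgt <- simulate_sas_mixture(basis, w_true, noise_rel = 0.01, seed = 55)
  pool <- c(basis, lapply(decoy_bead_models(20, seed = 56), debye_curve,
                          q_values = default_q_grid))
  ens <- ga_select(pool, tgt, seed = 57)
  # oracle: the true subset's chi2 from plain NNLS
  chi_true <- nnls_weights(basis, tgt)$chi2_red
  expect_lte(ens$chi2_red, chi_true + 1e-6)
  for (sp in names(w_true)) {
    got <- if (sp %in% names(ens$class_fractions))
      ens$class_fractions[[sp]] else 0
    expect_lt(abs(got - unname(w_true[sp])), 0.03)
  }
})

test_that("GA equals exhaustive enumeration on a small pool", {
  basis <- oligomer_basis()
  tgt <- simulate_sas_mixture(basis[c(1, 4)], c(0.8, 0.2),
                              noise_rel = 0.01, seed = 58)
  pool12 <- c(basis[1:2],
              lapply(decoy_bead_models(8, seed = 59), debye_curve,
                     q_values = default_q_grid),
              basis[3:4])
  ex <- ensemble_exhaustive(pool12, tgt, n_max = 3)
  hits <- vapply(1:20, function(s)
    ga_select(pool12, tgt, n_max = 3, seed = s)$chi2_red <=
      ex$chi2_red + 1e-9, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pools smaller than the ensemble size are rejected", {
  basis <- oligomer_basis()
  tgt <- basis[[1]]
  expect_error(ga_select(basis[1:2], tgt, n_max = 5), "pool")
})

test_that("ensemble weights are a probability vector", {
  basis <- oligomer_basis()
  tgt <- simulate_sas_mixture(basis, c(0.5, 0.2, 0.2, 0.1),
                              noise_rel = 0.01, seed = 60)
  ens <- ga_select(basis, tgt, n_max = 4, seed = 61)
  expect_true(all(ens$weights >= 0))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-6)
  expect_lte(length(ens$members), 4L)
})
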