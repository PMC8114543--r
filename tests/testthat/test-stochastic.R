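test_that("individual parameters follow the lognormal IIV model", {
  # degenerate variance: realized equals typical exactly
  ind <- sample_individuals(20, 1, var = variability_params(omega_cl = 0),
                            n = 5, seed = 1)
  expect_equal(ind$cl, rep(typical_clearance(20, 1), 5))
  expect_equal(ind$v, rep(typical_volume(20), 5))

  # large-sample moments of eta match omega^2 (variance convention)
  n <- 1e5
  ind <- sample_individuals(70, 0, var = variability_params(omega_cl = 0.175),
                            n = n, seed = 42)
  se_mean <- sqrt(0.175 / n)
  expect_lt(abs(mean(ind$eta_cl)), 3 * se_mean)
  se_var <- 0.175 * sqrt(2 / (n - 1))
  expect_lt(abs(var(ind$eta_cl) - 0.175), 3 * se_var)
  # lognormal median: median of exp(eta) near 1
  expect_equal(median(exp(ind$eta_cl)), 1, tolerance = 0.02)

  # determinism under a fixed seed
  a <- sample_individuals(70, 0, n = 10, seed = 7)
  b <- sample_individuals(70, 0, n = 10, seed = 7)
  expect_identical(a, b)

  # sd convention squares to the same draws as variance convention
  cv <- sample_individuals(70, 0, var = variability_params(0.175, scale = "variance"),
                           n = 10, seed = 3)
  cs <- sample_individuals(70, 0, var = variability_params(sqrt(0.175), scale = "sd"),
                           n = 10, seed = 3)
  expect_equal(cv$cl, cs$cl)
})

test_that("residual error laws behave as specified", {
  expect_equal(apply_residual_error(7, residual_error(sigma1 = 0)), 7)
  expect_equal(apply_residual_error(0, residual_error("proportional", 0.04),
                                    seed = 1), 0)
  n <- 1e5
  # additive: SD of O equals sigma (variance convention), independent of P
  for (pred in c(3, 12)) {
    o <- apply_residual_error(rep(pred, n), residual_error("additive", 1.913),
                              seed = 5)
    expect_equal(sd(o), sqrt(1.913), tolerance = 3 * sqrt(1 / (2 * n)) * 3)
    expect_equal(mean(o), pred, tolerance = 3 * sqrt(1.913 / n))
  }
  # proportional: constant CV across prediction levels
  cv <- vapply(c(4, 16), function(pred) {
    o <- apply_residual_error(rep(pred, n), residual_error("proportional", 0.04),
                              seed = 6)
    sd(o) / pred
  }, numeric(1))
  expect_equal(cv[1], cv[2], tolerance = 0.01)
  # combined includes both terms
  o <- apply_residual_error(rep(10, n), residual_error("combined", 0.04, 0.25),
                            seed = 8)
  expect_equal(var(o), 0.04 * 100 + 0.25, tolerance = 0.1)
  expect_error(residual_error("additive", sigma2 = 1), "combined")
  expect_error(residual_error("combined"), "sigma2")
  expect_error(residual_error(sigma1 = -1), "non-negative")
})

test_that("scale conversion and seed derivation are deterministic", {
  expect_equal(as_variance(1.913, "variance"), 1.913)
  expect_equal(as_variance(1.383, "sd"), 1.383^2)
  expect_error(as_variance(-1), "non-negative")
  expect_identical(derive_seed(42, "pta:qd"), derive_seed(42, "pta:qd"))
  expect_false(derive_seed(42, "pta:qd") == derive_seed(42, "pta:bid"))
  expect_false(derive_seed(42, "x") == derive_seed(43, "x"))
  s <- derive_seed(.Machine$integer.max, "boot")
  expect_true(s >= 1 && s <= 2^31 - 2)
})
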