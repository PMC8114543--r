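test_that("typical clearance follows the allometric covariate model", {
  expect_equal(typical_clearance(70, 0), 8.59)
  expect_equal(typical_clearance(70, 1), 8.59 * 1.16)
  # frozen from independent log-arithmetic evaluation of 8.59*(5/70)^0.75
  expect_equal(typical_clearance(5, 0), 1.186854, tolerance = 1e-6)
  # oxcarbazepine multiplies clearance by exactly theta_oxc at any weight
  for (w in c(5, 8, 20.5, 33, 68, 70))
    expect_equal(typical_clearance(w, 1) / typical_clearance(w, 0), 1.16)
  # strictly increasing in weight, but per-kg clearance decreases
  w <- seq(5, 70, by = 5)
  cl <- typical_clearance(w, 0)
  expect_true(all(diff(cl) > 0))
  expect_true(all(diff(cl / w) < 0))
  expect_error(typical_clearance(0, 0), "positive")
  expect_error(typical_clearance(-3, 0), "positive")
})

test_that("typical volume is linear in weight", {
  expect_equal(typical_volume(70), 294)
  expect_equal(typical_volume(35), 147)
  expect_equal(typical_volume(5), 294 * 5 / 70)
  expect_error(typical_volume(0), "positive")
})

test_that("steady-state trough matches the multi-dose ODE oracle", {
  skip_if_not_installed("deSolve")
  for (w in c(5, 10, 20, 40, 70)) {
    cl <- typical_clearance(w, 0); v <- typical_volume(w)
    for (tau in c(12, 24)) {
      dose <- 0.05 * w * (tau / 24)
      expect_equal(trough_steady_state(cl, v, dose, tau),
                   ode_trough_oracle(cl, v, dose, tau),
                   tolerance = 1e-6)
    }
  }
  # frozen oracle values: 2.1 mg q24h at 70 kg and 0.35 mg q24h at 5 kg
  expect_equal(trough_steady_state(8.59, 294, 2.1, 24), 7.479363,
               tolerance = 1e-5)
  expect_equal(trough_steady_state(1.186854, 21, 0.35, 24), 6.545162,
               tolerance = 1e-5)
})

test_that("trough is exactly dose-proportional and zero at zero dose", {
  expect_identical(trough_steady_state(8.59, 294, 0, 24), 0)
  t1 <- trough_steady_state(8.59, 294, 1.3, 24)
  expect_equal(trough_steady_state(8.59, 294, 2.6, 24), 2 * t1)
  expect_equal(trough_steady_state(8.59, 294, 13, 24), 10 * t1)
})

test_that("absorption-elimination degeneracy uses the continuous limit", {
  v <- 100; ka <- 0.485
  cl_eq <- ka * v # makes ke exactly ka
  near <- trough_steady_state(cl_eq * (1 + 1e-7), v, 5, 24, ka = ka)
  at <- trough_steady_state(cl_eq, v, 5, 24, ka = ka)
  expect_equal(at, near, tolerance = 1e-5)
})

test_that("concentration profile superposes doses and converges to the trough", {
  expect_identical(concentration_profile(8.59, 294, 2.1, 24, times = 0), 0)
  prof <- concentration_profile(8.59, 294, 2.1, 24, times = c(24, 240, 720))
  expect_equal(prof[3], trough_steady_state(8.59, 294, 2.1, 24),
               tolerance = 1e-6)
  expect_lt(prof[1], prof[2]) # accumulation
  expect_equal(concentration_profile(8.59, 294, 4.2, 24, times = c(12, 36, 240)),
               2 * concentration_profile(8.59, 294, 2.1, 24, times = c(12, 36, 240)))
  expect_error(concentration_profile(8.59, 294, 2.1, 24, times = c(10, 5)),
               "sorted")
  expect_error(concentration_profile(8.59, 294, 2.1, 24, times = -1),
               "non-negative")
})
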