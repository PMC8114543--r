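test_that("bootstrap bias formula is exact", {
  expect_equal(bias_percent(8.58, 8.59), (8.58 - 8.59) / 8.59 * 100)
  expect_equal(round(bias_percent(8.58, 8.59), 2), -0.12)
  expect_equal(bias_percent(10, 10), 0)
})

test_that("resampling identical subjects reproduces the original fit", {
  d <- make_manual_tdm(n_sub = 4, dv = c(6.8, 7.9, 7.1))
  f <- fit_popmodel(d, model_spec(), drop_small_eta = FALSE)
  b <- bootstrap_popmodel(d, f, n_reps = 3, seed = 2)
  expect_equal(b$n_converged, 3)
  for (r in seq_len(3))
    expect_equal(unname(b$replicates[r, ]), unname(f$estimates),
                 tolerance = 1e-5)
  expect_true(all(b$summary$lower <= b$summary$median + 1e-12))
  expect_true(all(b$summary$median <= b$summary$upper + 1e-12))
  expect_equal(b$summary$bias_pct,
               bias_percent(b$summary$median, b$summary$estimate))
})

test_that("bootstrap resampling stream is reproducible", {
  d <- generate_cohort(cohort_spec(n_subjects = 12, samples_mean = 2), seed = 4)
  f <- fit_popmodel(d, model_spec())
  b1 <- bootstrap_popmodel(d, f, n_reps = 4, seed = 11)
  b2 <- bootstrap_popmodel(d, f, n_reps = 4, seed = 11)
  expect_identical(b1$summary, b2$summary)
})

test_that("residuals vanish when observations equal predictions", {
  wt <- 70
  pred <- trough_steady_state(typical_clearance(wt, 0), typical_volume(wt),
                              2.1, 24)
  d <- make_manual_tdm(n_sub = 3, wt = wt, dv = rep(pred, 3))
  fake_fit <- structure(list(
    estimates = params_for(final_model_spec()),
    spec = final_model_spec(), nagq = 9L,
    eta = data.frame(id = 1:3, eta_cl = 0)), class = "popmodel_fit")
  g <- gof_diagnostics(d, fake_fit)
  expect_equal(g$pred, rep(pred, 9))
  expect_equal(g$ipred, g$pred)
  expect_equal(g$iwres, rep(0, 9))
  expect_equal(g$wres, rep(0, 9))
})

test_that("a constructed outlier is flagged by exactly one large |iWRES|", {
  pred <- trough_steady_state(typical_clearance(20, 0), typical_volume(20),
                              0.9, 24)
  dv <- rep(pred, 3)
  dv[2] <- pred + 10 * sqrt(1.913)
  d <- make_manual_tdm(n_sub = 1, wt = 20, dose = 0.9, dv = dv)
  fake_fit <- structure(list(
    estimates = params_for(final_model_spec()),
    spec = final_model_spec(), nagq = 9L,
    eta = data.frame(id = 1, eta_cl = 0)), class = "popmodel_fit")
  g <- gof_diagnostics(d, fake_fit)
  expect_equal(sum(abs(g$iwres) > 5), 1)
})

test_that("weighted residuals center at zero for self-consistent data", {
  f <- shared_fit()
  g <- gof_diagnostics(shared_cohort(), f)
  expect_lt(abs(mean(g$wres)), 3 / sqrt(nrow(g)))
  expect_lt(abs(sd(g$wres) - 1), 0.35)
})

test_that("VPC is seed-deterministic and bands collapse without variability", {
  f <- shared_fit()
  v1 <- vpc(shared_cohort(), f, n_sim = 25, seed = 6)
  v2 <- vpc(shared_cohort(), f, n_sim = 25, seed = 6)
  expect_identical(v1$bins, v2$bins)
  expect_true(all(v1$bins$sim_lo <= v1$bins$sim_med + 1e-12))
  expect_true(all(v1$bins$sim_med <= v1$bins$sim_hi + 1e-12))

  pred <- trough_steady_state(typical_clearance(30, 0), typical_volume(30),
                              1.4, 24)
  d <- make_manual_tdm(n_sub = 6, wt = 30, dose = 1.4, dv = rep(pred, 2))
  fake <- structure(list(
    estimates = c(theta_cl = 8.59, theta_v = 294, theta_oxc = 1.16,
                  omega2_cl = 0, sigma2_1 = 0),
    spec = final_model_spec(), nagq = 1L,
    eta = data.frame(id = 1:6, eta_cl = 0)), class = "popmodel_fit")
  suppressWarnings(v0 <- vpc(d, fake, n_sim = 10, seed = 1))
  expect_equal(v0$bins$sim_lo, v0$bins$sim_hi)
  expect_equal(v0$bins$sim_med, v0$bins$obs_med)
})
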