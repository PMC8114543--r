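test_that("generated cohorts match the study's demographic structure", {
  d <- shared_cohort()
  n <- length(unique(d$ID))
  expect_equal(n, 80)
  n_obs <- sum(d$EVID == 0)
  # 1 + Poisson(1.35) troughs per subject: mean 188 total, binomial-ish SD
  expect_gt(n_obs, 188 - 3 * sqrt(80 * 1.35))
  expect_lt(n_obs, 188 + 3 * sqrt(80 * 1.35))
  sub <- d[d$EVID == 1, ]
  expect_lt(abs(mean(sub$WT) - 23.50), 3 * 11.71 / sqrt(80))
  expect_true(all(sub$WT >= 8 & sub$WT <= 68))
  p_oxc <- 23 / 80
  expect_lt(abs(mean(sub$OXC) - p_oxc), 3 * sqrt(p_oxc * (1 - p_oxc) / 80))
  expect_true(all(d$DV[d$EVID == 0] > 0))
  # bit-reproducible under a fixed seed
  expect_identical(generate_cohort(cohort_spec(), seed = 424), d)
})

test_that("zero variability reproduces the deterministic model output", {
  sp <- cohort_spec(n_subjects = 1, weight_range = c(69.9, 70.1),
                    weight_mean = 70, weight_sd = 0.01, oxc_prevalence = 0,
                    samples_mean = 3,
                    dose_policy = list(type = "fixed", dose_mg = 2.1),
                    var = variability_params(omega_cl = 0),
                    err = residual_error(sigma1 = 0))
  d <- generate_cohort(sp, seed = 2)
  expected <- round(trough_steady_state(typical_clearance(d$WT[1], 0),
                                        typical_volume(d$WT[1]), 2.1, 24), 2)
  expect_true(all(d$DV[d$EVID == 0] == expected))
  expect_equal(expected, 7.48, tolerance = 0.01)
})

test_that("a single-subject cohort passes all dataset invariants", {
  d <- generate_cohort(cohort_spec(n_subjects = 1), seed = 9)
  expect_s3_class(validate_tdm(d), "tdm_data")
  expect_equal(unique(d$ID), 1)
})

test_that("dataset I/O round-trips and rejects malformed files", {
  d <- shared_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tdm(d, path)
  r <- read_tdm(path)
  expect_equal(as.data.frame(r), as.data.frame(d), ignore_attr = TRUE)

  # DV on a dose row violates the event-type invariant
  bad <- as.data.frame(d)
  bad$DV[which(bad$EVID == 1)[1]] <- 5
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_tdm(path2), "dose row")

  # empty file
  path3 <- withr::local_tempfile(fileext = ".csv")
  file.create(path3)
  expect_error(read_tdm(path3), "empty")
  expect_error(read_tdm(tempfile()), "no such file")
})

test_that("cohort spec rejects infeasible settings", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(oxc_prevalence = 1.2), "prevalences")
  expect_error(cohort_spec(weight_range = c(50, 10)), "infeasible")
  expect_error(cohort_spec(samples_mean = 0.5), "samples_mean")
})
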