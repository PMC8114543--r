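test_that("Gauss-Hermite rule integrates polynomial moments exactly", {
  gh <- gauss_hermite(9)
  # integral x^k e^{-x^2}: sqrt(pi), 0, sqrt(pi)/2, 0, 3 sqrt(pi)/4
  expect_equal(sum(gh$weights), sqrt(pi))
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4)
})

test_that("objective matches brute-force quadrature on toy datasets", {
  spec <- final_model_spec()
  p <- params_for(spec)
  # single subject, single observation
  d1 <- make_manual_tdm(n_sub = 1, dv = 7.2)
  expect_equal(ofv(d1, spec, p), brute_force_ofv(d1, p),
               tolerance = 1e-4)
  # three subjects, sparse generated data
  d3 <- generate_cohort(cohort_spec(n_subjects = 3, samples_mean = 2),
                        seed = 31)
  expect_equal(ofv(d3, spec, p), brute_force_ofv(d3, p), tolerance = 1e-4)
  # also away from the generating parameters
  p2 <- p
  p2["theta_cl"] <- 12; p2["omega2_cl"] <- 0.4; p2["sigma2_1"] <- 1.2
  expect_equal(ofv(d3, spec, p2), brute_force_ofv(d3, p2), tolerance = 1e-4)
})

test_that("degenerate variance reduces the OFV to the WLS deviance", {
  spec <- final_model_spec()
  p <- params_for(spec)
  p["omega2_cl"] <- 0
  d <- make_manual_tdm(n_sub = 2, dv = c(6.9, 7.8))
  f <- trough_steady_state(typical_clearance(70, 0), 294, 2.1, 24)
  s2 <- p[["sigma2_1"]]
  dev_per_subject <- sum(log(2 * pi * s2) + (c(6.9, 7.8) - f)^2 / s2)
  expect_equal(ofv(d, spec, p), 2 * dev_per_subject, tolerance = 1e-10)
})

test_that("OFV is additive over subjects and invariant to ordering", {
  spec <- final_model_spec()
  p <- params_for(spec)
  d1 <- make_manual_tdm(n_sub = 1, dv = c(6.5, 8.2))
  d2 <- make_manual_tdm(n_sub = 2, dv = c(6.5, 8.2))
  expect_equal(ofv(d2, spec, p), 2 * ofv(d1, spec, p), tolerance = 1e-8)

  d <- generate_cohort(cohort_spec(n_subjects = 8), seed = 5)
  base <- ofv(d, spec, params_for(spec))
  # reverse subject blocks
  ids <- unique(d$ID)
  shuf <- do.call(rbind, lapply(rev(ids), function(i) d[d$ID == i, ]))
  class(shuf) <- class(d)
  expect_equal(ofv(shuf, spec, params_for(spec)), base, tolerance = 1e-10)
  # permute observation rows within a subject (dose row stays first)
  s1 <- which(d$ID == ids[1])
  obs1 <- s1[d$EVID[s1] == 0]
  if (length(obs1) > 1) {
    perm <- seq_len(nrow(d))
    perm[obs1] <- rev(obs1)
    d2 <- d[perm, ]
    d2$TIME[d2$ID == ids[1] & d2$EVID == 0] <-
      sort(d2$TIME[d2$ID == ids[1] & d2$EVID == 0])
    class(d2) <- class(d)
    expect_equal(ofv(d2, spec, params_for(spec)), base, tolerance = 1e-10)
  }
})

test_that("non-finite predictions yield the +Inf sentinel", {
  spec <- final_model_spec()
  p <- params_for(spec)
  p["theta_cl"] <- -1
  expect_identical(ofv(make_manual_tdm(1, dv = 7), spec, p), Inf)
  p2 <- params_for(spec)
  p2["sigma2_1"] <- 0
  expect_identical(ofv(make_manual_tdm(1, dv = 7), spec, p2), Inf)
})
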