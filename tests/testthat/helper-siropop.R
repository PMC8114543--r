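# Shared fixtures, all generated in code.

# independent multi-dose ODE oracle for the steady-state trough (deSolve)
ode_trough_oracle <- function(cl, v, dose_mg, interval, ka = 0.485,
                              n_doses = 80) {
  derivs <- function(t, y, p) {
    list(c(-p$ka * y[1], p$ka * y[1] - p$ke * y[2]))
  }
  dose_times <- (seq_len(n_doses) - 1) * interval
  out <- deSolve::lsoda(
    y = c(A1 = 0, A2 = 0), times = c(dose_times, n_doses * interval),
    func = derivs, parms = list(ka = ka, ke = cl / v),
    events = list(data = data.frame(var = "A1", time = dose_times,
                                    value = dose_mg, method = "add")),
    rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), "A2"]) / v * 1000
}

# brute-force -2 log marginal likelihood by adaptive 1-D quadrature,
# independent of the package's Laplace/Gauss-Hermite path
brute_force_ofv <- function(data, p) {
  data <- as.data.frame(data)
  obs_all <- data[data$EVID == 0, ]
  doses <- data[data$EVID == 1, ]
  total <- 0
  o2 <- p[["omega2_cl"]]; s2 <- p[["sigma2_1"]]
  th_oxc <- if ("theta_oxc" %in% names(p)) p[["theta_oxc"]] else 1
  for (id in unique(obs_all$ID)) {
    s <- obs_all[obs_all$ID == id, ]
    amt <- doses$AMT[match(id, doses$ID)]
    ii <- doses$II[match(id, doses$ID)]
    tvcl <- p[["theta_cl"]] * (s$WT / 70)^0.75 * th_oxc^s$OXC
    tvv <- p[["theta_v"]] * (s$WT / 70)
    integrand <- Vectorize(function(eta) {
      ke <- tvcl[1] * exp(eta) / tvv[1]
      f <- (amt * 0.485) / (tvv * (0.485 - ke)) *
        (exp(-ke * ii) / (1 - exp(-ke * ii)) -
         exp(-0.485 * ii) / (1 - exp(-0.485 * ii))) * 1000
      exp(sum(stats::dnorm(s$DV, f, sqrt(s2), log = TRUE)) +
            stats::dnorm(eta, 0, sqrt(o2), log = TRUE))
    })
    L <- stats::integrate(integrand, -10 * sqrt(o2), 10 * sqrt(o2),
                          rel.tol = 1e-12, abs.tol = 0)$value
    total <- total - 2 * log(L)
  }
  total
}

# hand-built deterministic dataset: n identical subjects, given DV values
make_manual_tdm <- function(n_sub = 3, wt = 70, oxc = 0, dose = 2.1,
                            ii = 24, dv = c(7.2, 7.6)) {
  rows <- lapply(seq_len(n_sub), function(i) {
    data.frame(ID = i, TIME = c(0, seq_along(dv) * ii * 30),
               EVID = c(1L, rep(0L, length(dv))),
               AMT = c(dose, rep(NA_real_, length(dv))),
               DV = c(NA_real_, dv), MDV = c(1L, rep(0L, length(dv))),
               II = ii, WT = wt, OXC = oxc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tdm_data", "data.frame")
  out
}

# medium cohort + fit, built once per test run and cached
.shared <- new.env()
shared_cohort <- function() {
  if (is.null(.shared$data))
    .shared$data <- generate_cohort(cohort_spec(), seed = 424)
  .shared$data
}
shared_fit <- function() {
  if (is.null(.shared$fit))
    .shared$fit <- fit_popmodel(shared_cohort(), final_model_spec())
  .shared$fit
}
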