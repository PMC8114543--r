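# Model validation: nonparametric bootstrap, goodness-of-fit residual
# diagnostics and prediction-corrected visual predictive check.

#' Percent bias of a bootstrap median against the point estimate
#'
#' `bias = (median - estimate) / estimate x 100`.
#'
#' @param median_rep median of the replicate estimates.
#' @param estimate original point estimate.
#' @return bias in percent.
#' @examples
#' bias_percent(8.58, 8.59) # -0.116...
#' @export
bias_percent <- function(median_rep, estimate) {
  (median_rep - estimate) / estimate * 100
}

#' Nonparametric bootstrap of the population-model fit
#'
#' Resamples subjects (the longitudinal resampling unit) with
#' replacement, refits each replicate dataset starting from the original
#' estimates, and summarizes each parameter by the median and
#' 2.5th / 97.5th percentiles of the converged replicates, with
#' `bias = (median - estimate) / estimate x 100`.
#'
#' @param data a `tdm_data` dataset.
#' @param fit the original [fit_popmodel()] result.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed for the reproducible resampling stream.
#' @param ... passed to [fit_popmodel()] for the replicate fits.
#' @return an object of class `popmodel_bootstrap`: `summary`
#'   data.frame (estimate, median, lower, upper, bias_pct), `replicates`
#'   matrix, `n_converged`, `failed` flag (> 50% non-convergence).
#' @export
bootstrap_popmodel <- function(data, fit, n_reps = 1000, seed = 1, ...) {
  data <- validate_tdm(data)
  stopifnot(inherits(fit, "popmodel_fit"))
  ids <- unique(data$ID)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  draws <- matrix(sample(ids, length(ids) * n_reps, replace = TRUE),
                  nrow = n_reps)
  reps <- matrix(NA_real_, n_reps, length(fit$estimates),
                 dimnames = list(NULL, names(fit$estimates)))
  conv <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    take <- draws[r, ]
    pieces <- lapply(seq_along(take), function(k) {
      sub <- data[data$ID == take[k], , drop = FALSE]
      sub$ID <- k
      sub
    })
    bd <- do.call(rbind, pieces)
    class(bd) <- class(data)
    f <- try(fit_popmodel(bd, fit$spec, init = fit$estimates,
                          nagq = fit$nagq, drop_small_eta = FALSE, ...),
             silent = TRUE)
    if (!inherits(f, "try-error") && f$converged &&
        all(names(fit$estimates) %in% names(f$estimates))) {
      reps[r, ] <- f$estimates[names(fit$estimates)]
      conv[r] <- TRUE
    }
  }
  ok <- reps[conv, , drop = FALSE]
  summ <- data.frame(
    parameter = names(fit$estimates),
    estimate = unname(fit$estimates),
    median = apply(ok, 2, stats::median),
    lower = apply(ok, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(ok, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL)
  summ$bias_pct <- bias_percent(summ$median, summ$estimate)
  structure(list(summary = summ, replicates = ok,
                 n_reps = n_reps, n_converged = sum(conv),
                 failed = sum(conv) < n_reps / 2),
            class = "popmodel_bootstrap")
}

#' @export
print.popmodel_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged%s\n", x$n_converged,
              x$n_reps, if (x$failed) " -- FAILED (>50% non-convergence)" else ""))
  print(transform(x$summary,
                  median = signif(median, 4), lower = signif(lower, 4),
                  upper = signif(upper, 4), bias_pct = round(bias_pct, 2)))
  invisible(x)
}

#' Goodness-of-fit residual diagnostics
#'
#' Per-observation population predictions (PRED, at eta = 0),
#' individual predictions (IPRED, at the empirical-Bayes eta), the
#' individual weighted residual `iWRES = (DV - IPRED) / sd(IPRED)`, and
#' a conditional weighted residual (WRES) based on the first-order
#' linearization of the model around the empirical-Bayes eta with the
#' full per-subject covariance — approximately standard normal under a
#' correct model.
#'
#' @param data a `tdm_data` dataset.
#' @param fit a converged [fit_popmodel()] result.
#' @return data.frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `iwres`, `wres`.
#' @export
gof_diagnostics <- function(data, fit) {
  data <- validate_tdm(data)
  spec <- fit$spec
  obj <- .make_objfun(data, spec, nagq = fit$nagq)
  obs <- obj$obs
  est <- fit$estimates
  tvs <- obj$tv(est)
  s2 <- obj$s2_of(est)
  if (s2$s1 <= 0) stop("zero residual variance; diagnostics undefined")
  eta <- fit$eta
  d <- length(spec$eta)
  has_cl <- "cl" %in% spec$eta
  has_v <- "v" %in% spec$eta
  omega <- diag(c(if (has_cl) est[["omega2_cl"]], if (has_v) est[["omega2_v"]]),
                nrow = d)

  pred_at <- function(eta_row, rows) {
    cl <- tvs$cl[rows]; v <- tvs$v[rows]
    k <- 1
    if (has_cl) { cl <- cl * exp(eta_row[k]); k <- k + 1 }
    if (has_v)  v <- v * exp(eta_row[k])
    trough_steady_state(cl, v, obs$amt[rows], obs$ii[rows], ka = spec$ka)
  }

  pred <- trough_steady_state(tvs$cl, tvs$v, obs$amt, obs$ii, ka = spec$ka)
  ipred <- wres <- numeric(nrow(obs))
  h <- 1e-5
  for (i in seq_len(obj$n_sub)) {
    rows <- which(obj$sidx == i)
    ei <- as.numeric(eta[i, -1, drop = FALSE])
    fi <- pred_at(ei, rows)
    ipred[rows] <- fi
    # linearization gradient G (n_obs_i x d)
    G <- vapply(seq_len(d), function(k) {
      ep <- ei; ep[k] <- ep[k] + h
      em <- ei; em[k] <- em[k] - h
      (pred_at(ep, rows) - pred_at(em, rows)) / (2 * h)
    }, numeric(length(rows)))
    G <- matrix(G, ncol = d)
    mu <- fi - as.numeric(G %*% ei)
    V <- G %*% omega %*% t(G) + diag(.res_var(fi, s2), nrow = length(rows))
    wres[rows] <- solve(t(chol(V)), obs$dv[rows] - mu)
  }
  iwres <- (obs$dv - ipred) / sqrt(.res_var(ipred, s2))
  times <- as.data.frame(data)[data$EVID == 0, "TIME"]
  data.frame(id = obs$id, time = times, dv = obs$dv, pred = pred,
             ipred = ipred, iwres = iwres, wres = wres)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design under the
#' fitted model, prediction-corrects observed and simulated
#' concentrations (values scaled by the ratio of the bin-median
#' population prediction to each observation's population prediction),
#' bins by weight quartile (trough sampling times carry no information),
#' and compares observed percentiles with the simulated 2.5-97.5%
#' band.  Bins with fewer than two observations are merged with a
#' warning.
#'
#' @param data a `tdm_data` dataset.
#' @param fit a converged [fit_popmodel()] result.
#' @param n_sim number of simulated replicate datasets.
#' @param seed integer seed.
#' @return an object of class `popmodel_vpc`: per-bin observed
#'   percentiles, simulated band (pooled 2.5/50/97.5 percentiles),
#'   across-simulation confidence intervals for each percentile, and
#'   the overall observed-within-band `coverage`.
#' @export
vpc <- function(data, fit, n_sim = 1000, seed = 1) {
  data <- validate_tdm(data)
  obj <- .make_objfun(data, fit$spec, nagq = fit$nagq)
  obs <- obj$obs
  est <- fit$estimates
  tvs <- obj$tv(est)
  s2 <- obj$s2_of(est)
  spec <- fit$spec
  pred <- trough_steady_state(tvs$cl, tvs$v, obs$amt, obs$ii, ka = spec$ka)

  # weight-quartile bins; coarsen (merge) while any bin is too sparse
  for (k in c(4, 2, 1)) {
    br <- unique(stats::quantile(obs$wt, seq(0, 1, length.out = k + 1)))
    if (length(br) < 2) br <- range(obs$wt) + c(-1, 1)
    bin <- cut(obs$wt, br, include.lowest = TRUE)
    if (all(table(bin) >= 2) || k == 1) break
    warning("merging sparse VPC bins")
  }
  binmed <- tapply(pred, bin, stats::median)
  pc_obs <- obs$dv * binmed[bin] / pred

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d <- length(spec$eta)
  has_cl <- "cl" %in% spec$eta
  has_v <- "v" %in% spec$eta
  o2cl <- if (has_cl) est[["omega2_cl"]] else 0
  o2v <- if (has_v) est[["omega2_v"]] else 0
  err <- residual_error(kind = spec$error, sigma1 = s2$s1,
                        sigma2 = s2$s2, scale = "variance")

  qs <- c(0.025, 0.5, 0.975)
  sim_pc <- matrix(NA_real_, n_sim, length(pc_obs))
  sim_q <- array(NA_real_, c(n_sim, nlevels(factor(bin)), 3))
  binf <- factor(bin)
  for (s in seq_len(n_sim)) {
    ecl <- if (o2cl > 0) stats::rnorm(obj$n_sub, 0, sqrt(o2cl)) else numeric(obj$n_sub)
    ev <- if (o2v > 0) stats::rnorm(obj$n_sub, 0, sqrt(o2v)) else numeric(obj$n_sub)
    f <- trough_steady_state(tvs$cl * exp(ecl[obj$sidx]),
                             tvs$v * exp(ev[obj$sidx]),
                             obs$amt, obs$ii, ka = spec$ka)
    y <- apply_residual_error(pmax(f, 0), err)
    pc <- y * binmed[bin] / pred
    sim_pc[s, ] <- pc
    for (b in seq_len(nlevels(binf)))
      sim_q[s, b, ] <- stats::quantile(pc[binf == levels(binf)[b]], qs)
  }

  per_bin <- lapply(levels(binf), function(b) {
    sel <- binf == b
    band <- stats::quantile(sim_pc[, sel], qs, names = FALSE)
    data.frame(bin = b, n = sum(sel),
               obs_lo = stats::quantile(pc_obs[sel], 0.025, names = FALSE),
               obs_med = stats::median(pc_obs[sel]),
               obs_hi = stats::quantile(pc_obs[sel], 0.975, names = FALSE),
               sim_lo = band[1], sim_med = band[2], sim_hi = band[3])
  })
  per_bin <- do.call(rbind, per_bin)
  lo <- per_bin$sim_lo[match(binf, per_bin$bin)]
  hi <- per_bin$sim_hi[match(binf, per_bin$bin)]
  coverage <- mean(pc_obs >= lo & pc_obs <= hi)

  ci <- apply(sim_q, c(2, 3), stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  structure(list(bins = per_bin, coverage = coverage, n_sim = n_sim,
                 pc_obs = data.frame(bin = binf, wt = obs$wt, pc = pc_obs),
                 percentile_ci = ci, binning = "weight quartiles"),
            class = "popmodel_vpc")
}

#' @export
print.popmodel_vpc <- function(x, ...) {
  cat(sprintf("pcVPC (%s, %d simulations): %.1f%% of observations inside the 2.5-97.5%% band\n",
              x$binning, x$n_sim, 100 * x$coverage))
  print(transform(x$bins, obs_lo = signif(obs_lo, 3), obs_med = signif(obs_med, 3),
                  obs_hi = signif(obs_hi, 3), sim_lo = signif(sim_lo, 3),
                  sim_med = signif(sim_med, 3), sim_hi = signif(sim_hi, 3)))
  invisible(x)
}
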