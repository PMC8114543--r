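# Maximum (approximate marginal) likelihood fitting and OFV-based
# stepwise covariate selection.

# transform/untransform between natural and optimizer scales: log for
# strictly positive parameters, identity for continuous-covariate
# exponents (which may be negative)
.par_transform <- function(spec) {
  nm <- names(params_for(spec))
  is_log <- !grepl("^theta_", nm) | nm %in% c("theta_cl", "theta_v")
  for (cv in names(spec$covariates)) {
    pn <- paste0("theta_", tolower(cv))
    is_log[nm == pn] <- spec$covariates[[cv]] == "categorical"
  }
  list(names = nm,
       to = function(p) ifelse(is_log, log(p), p),
       from = function(q) {
         p <- ifelse(is_log, exp(q), q)
         names(p) <- nm
         p
       })
}

# default starting values: cheap naive estimates, robust to poor data
.default_init <- function(spec, obj) {
  obs <- obj$obs
  # naive clearance per observation assuming trough ~ dose-proportional
  p <- c(theta_cl = 10, theta_v = 300)
  for (cv in names(spec$covariates)) {
    p[paste0("theta_", tolower(cv))] <-
      if (spec$covariates[[cv]] == "categorical") 1 else 0.01
  }
  if ("cl" %in% spec$eta) p["omega2_cl"] <- 0.1
  if ("v" %in% spec$eta) p["omega2_v"] <- 0.1
  mdv <- stats::median(obs$dv)
  p["sigma2_1"] <- switch(spec$error, additive = max(0.2 * mdv, 0.5)^2,
                          proportional = 0.04, combined = 0.04)
  if (spec$error == "combined") p["sigma2_2"] <- 0.25
  p
}

#' Fit the population model to a TDM dataset
#'
#' Minimizes the approximate marginal -2 log-likelihood ([ofv()]) over
#' the fixed effects, variability and residual-error parameters.
#' Positive parameters are optimized on the log scale with
#' [stats::nlminb()]; standard errors come from the inverse of half the
#' numerical Hessian of the OFV at the optimum (the observed
#' information); empirical-Bayes eta estimates are returned per subject.
#'
#' When `drop_small_eta = TRUE` (default) and the fitted variance of a
#' random effect is below `1e-4`, the model is refitted without that
#' random effect — the "estimated near zero, so dropped" rule used for
#' the volume IIV in the final model.
#'
#' @param data a `tdm_data` dataset.
#' @param spec a [model_spec()].
#' @param init optional named starting values (natural scale).
#' @param nagq quadrature nodes (see [ofv()]).
#' @param drop_small_eta drop random effects whose fitted variance is
#'   below 1e-4 and refit.
#' @param exclude_blq drop observations below the assay's lower limit of
#'   linear response (3.5 ng/ml, or the dataset's `blq_limit` attribute)
#'   before fitting; the default keeps them as recorded.
#' @param control passed to [stats::nlminb()].
#' @return an object of class `popmodel_fit`: list with `estimates`,
#'   `se`, `ofv`, `eta` (empirical-Bayes), `converged`, `spec`, `notes`.
#' @export
fit_popmodel <- function(data, spec = final_model_spec(), init = NULL,
                         nagq = 9L, drop_small_eta = TRUE,
                         exclude_blq = FALSE,
                         control = list(iter.max = 400, eval.max = 600)) {
  data <- validate_tdm(data)
  if (exclude_blq) {
    lim <- attr(data, "blq_limit")
    if (is.null(lim)) lim <- 3.5
    keep <- data$EVID != 0 | data$DV >= lim
    data <- validate_tdm(data[keep, , drop = FALSE])
  }
  obj <- .make_objfun(data, spec, nagq = nagq)
  tr <- .par_transform(spec)
  p0 <- .default_init(spec, obj)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(p0))
    if (length(bad)) stop("unknown init parameter(s): ", paste(bad, collapse = ", "))
    p0[names(init)] <- init
  }
  q0 <- tr$to(p0)
  fobj <- function(q) obj$fn(tr$from(q))
  opt <- stats::nlminb(q0, fobj, control = control)
  est <- tr$from(opt$par)
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  notes <- character()
  if (!converged) notes <- c(notes, paste0("nlminb: ", opt$message))

  if (drop_small_eta) {
    small <- grep("^omega2_", names(est), value = TRUE)
    small <- small[est[small] < 1e-4]
    small <- sub("^omega2_", "", small)
    if (length(small) && length(spec$eta) > length(small)) {
      spec2 <- spec
      spec2$eta <- setdiff(spec$eta, small)
      notes <- c(notes, paste0("dropped eta on ", paste(small, collapse = ", "),
                               " (variance < 1e-4) and refitted"))
      keep <- !(names(est) %in% paste0("omega2_", small))
      res <- fit_popmodel(data, spec2, init = est[keep], nagq = nagq,
                          drop_small_eta = FALSE, control = control)
      res$notes <- c(notes, res$notes)
      return(res)
    }
  }

  # observed information: OFV = -2 logL, so Var = 2 * H^{-1}
  se <- rep(NA_real_, length(est)); names(se) <- names(est)
  vcov <- NULL
  H <- try(stats::optimHess(est, obj$fn), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H / 2), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      se <- sqrt(diag(V)); names(se) <- names(est)
      vcov <- V
    } else notes <- c(notes, "Hessian not positive definite; SEs unavailable")
  } else notes <- c(notes, "Hessian evaluation failed; SEs unavailable")

  structure(list(estimates = est, se = se, vcov = vcov,
                 ofv = opt$objective, eta = obj$ebe(est),
                 converged = converged, iterations = opt$iterations,
                 spec = spec, nagq = nagq, n_sub = obj$n_sub,
                 n_obs = obj$n_obs, notes = notes),
            class = "popmodel_fit")
}

#' @export
print.popmodel_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations\n",
              x$n_sub, x$n_obs))
  cat(sprintf("OFV %.3f (%s, %d quadrature node%s)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged",
              x$nagq, if (x$nagq > 1) "s" else ""))
  tab <- data.frame(Estimate = signif(x$estimates, 4),
                    SE = signif(x$se, 3))
  print(tab)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Coerce fit results to the parameter objects
#'
#' @param fit a `popmodel_fit`.
#' @return a list with `fx` ([fixed_effects()]), `var`
#'   ([variability_params()]) and `err` ([residual_error()]) holding the
#'   fitted values (variance scale).
#' @export
fitted_params <- function(fit) {
  e <- fit$estimates
  fx <- fixed_effects(theta_cl = e[["theta_cl"]], theta_v = e[["theta_v"]],
                      theta_oxc = if ("theta_oxc" %in% names(e)) e[["theta_oxc"]] else 1,
                      power_cl = fit$spec$power_cl, power_v = fit$spec$power_v,
                      w_std = fit$spec$w_std, ka_fixed = fit$spec$ka)
  var <- variability_params(
    omega_cl = if ("omega2_cl" %in% names(e)) e[["omega2_cl"]] else 0,
    omega_v = if ("omega2_v" %in% names(e)) e[["omega2_v"]] else NULL,
    scale = "variance")
  err <- residual_error(kind = fit$spec$error, sigma1 = e[["sigma2_1"]],
                        sigma2 = if ("sigma2_2" %in% names(e)) e[["sigma2_2"]] else NULL,
                        scale = "variance")
  list(fx = fx, var = var, err = err)
}

#' Stepwise covariate selection by objective-function change
#'
#' Forward inclusion then backward elimination on clearance covariates.
#' A candidate enters when it lowers the OFV by more than 3.84
#' (chi-squared, p < 0.05, 1 df); at each forward round the candidate
#' with the largest drop is added first (ties broken by candidate list
#' order).  In the backward step each included covariate is removed in
#' turn and retained only when its removal raises the OFV by more than
#' 6.63 (p < 0.01).  Constant or collinear candidates are skipped with a
#' warning.  The full decision trail is returned.
#'
#' @param data a `tdm_data` dataset.
#' @param base_spec the [model_spec()] to start from (no candidates).
#' @param candidates named character vector of candidate covariates,
#'   as in [model_spec()]'s `covariates` argument.
#' @param forward_dofv,backward_dofv OFV-change thresholds.
#' @param ... passed to [fit_popmodel()].
#' @return list with `spec` (selected model), `fit` (its fit), `trail`
#'   (data.frame decision log) and `selected` (covariate names).
#' @export
covariate_screen <- function(data, base_spec = model_spec(), candidates,
                             forward_dofv = 3.84, backward_dofv = 6.63,
                             ...) {
  data <- validate_tdm(data)
  if (!length(candidates)) {
    fit <- fit_popmodel(data, base_spec, ...)
    return(list(spec = base_spec, fit = fit,
                trail = data.frame(), selected = character()))
  }
  trail <- list()
  note_row <- function(phase, cand, ofv_ref, ofv_new, dofv, decision)
    data.frame(phase = phase, covariate = cand, ofv_ref = ofv_ref,
               ofv_new = ofv_new, dofv = dofv, decision = decision)

  # candidate fits warm-start from the current model's estimates
  fit_with <- function(covs, from = NULL) {
    sp <- base_spec
    sp$covariates <- covs
    init <- NULL
    if (!is.null(from)) {
      keep <- names(from$estimates) %in% names(params_for(sp))
      init <- from$estimates[keep]
    }
    fit_popmodel(data, sp, init = init, ...)
  }

  # drop unusable candidates up-front
  usable <- character()
  for (nm in names(candidates)) {
    col <- data[[nm]]
    if (is.null(col) || length(unique(col[data$EVID == 0])) < 2) {
      warning("skipping constant or missing candidate: ", nm)
      trail[[length(trail) + 1]] <- note_row("precheck", nm, NA, NA, NA, "skipped")
    } else usable <- c(usable, nm)
  }
  candidates <- candidates[usable]

  base_fit <- fit_popmodel(data, base_spec, ...)
  current <- character()  # names of included candidates
  current_fit <- base_fit

  repeat {
    remaining <- setdiff(names(candidates), current)
    if (!length(remaining)) break
    drops <- rep(-Inf, length(remaining)); names(drops) <- remaining
    fits <- list()
    for (nm in remaining) {
      f <- try(fit_with(candidates[c(current, nm)], from = current_fit),
               silent = TRUE)
      if (inherits(f, "try-error") || !is.finite(f$ofv)) {
        warning("candidate fit failed: ", nm)
        trail[[length(trail) + 1]] <-
          note_row("forward", nm, current_fit$ofv, NA, NA, "fit failed")
        next
      }
      fits[[nm]] <- f
      drops[nm] <- current_fit$ofv - f$ofv
      trail[[length(trail) + 1]] <-
        note_row("forward", nm, current_fit$ofv, f$ofv, drops[nm],
                 if (drops[nm] > forward_dofv) "eligible" else "not significant")
    }
    best <- which.max(drops)   # first max wins: candidate-list order breaks ties
    if (!length(best) || drops[best] <= forward_dofv) break
    nm <- names(drops)[best]
    current <- c(current, nm)
    current_fit <- fits[[nm]]
    trail[[length(trail) + 1]] <-
      note_row("forward", nm, NA, current_fit$ofv, drops[best], "included")
  }

  # backward elimination at the stricter threshold
  for (nm in current) {
    reduced <- setdiff(current, nm)
    f <- if (length(reduced)) fit_with(candidates[reduced], from = current_fit)
         else base_fit
    dofv <- f$ofv - current_fit$ofv
    keep <- dofv > backward_dofv
    trail[[length(trail) + 1]] <-
      note_row("backward", nm, current_fit$ofv, f$ofv, dofv,
               if (keep) "retained" else "removed")
    if (!keep) {
      current <- reduced
      current_fit <- f
    }
  }

  sp <- base_spec
  sp$covariates <- candidates[current]
  list(spec = sp, fit = current_fit,
       trail = do.call(rbind, c(trail, list(make.row.names = FALSE))),
       selected = current)
}
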