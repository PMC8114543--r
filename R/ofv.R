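# Approximate marginal likelihood (-2 log L, "OFV") for the nonlinear
# mixed-effects trough model.  Each subject's integral over eta is
# evaluated by adaptive Gauss-Hermite quadrature centered and scaled at
# the conditional mode (the 1-node case is the classical Laplace
# approximation); the residual variance is evaluated at the conditional
# prediction, i.e. "with interaction".

#' Mixed-effects model specification
#'
#' Describes which model is fitted: the structural model is fixed (one
#' compartment, first-order absorption with Ka not estimated, allometric
#' weight scaling with fixed exponents 0.75 / 1 at a 70 kg reference),
#' so the spec selects the residual-error law, which parameters carry a
#' random effect, and which covariate effects on clearance are
#' estimated: categorical covariates enter as `theta^x` (indicator
#' exponent), continuous ones as `(x / median)^theta`.
#'
#' @param error residual-error kind: `"additive"`, `"proportional"` or
#'   `"combined"`.
#' @param eta character subset of `c("cl", "v")`: parameters carrying a
#'   lognormal random effect.  At least one is required.
#' @param covariates named character vector mapping dataset column names
#'   (e.g. `"OXC"`) to `"categorical"` or `"continuous"`.
#' @param ka fixed absorption rate constant (1/h).
#' @param w_std,power_cl,power_v allometric reference weight and fixed
#'   exponents.
#' @return an object of class `model_spec`.
#' @examples
#' final_model_spec() # the published final model structure
#' @export
model_spec <- function(error = c("additive", "proportional", "combined"),
                       eta = "cl",
                       covariates = character(),
                       ka = 0.485, w_std = 70,
                       power_cl = 0.75, power_v = 1) {
  error <- match.arg(error)
  eta <- match.arg(eta, c("cl", "v"), several.ok = TRUE)
  if (!length(eta)) stop("at least one random effect is required")
  if (length(covariates) &&
      (!all(covariates %in% c("categorical", "continuous")) ||
       is.null(names(covariates)) || any(!nzchar(names(covariates)))))
    stop("covariates must be a named vector of 'categorical'/'continuous'")
  structure(list(error = error, eta = eta, covariates = covariates,
                 ka = ka, w_std = w_std,
                 power_cl = power_cl, power_v = power_v),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
final_model_spec <- function() {
  model_spec(error = "additive", eta = "cl",
             covariates = c(OXC = "categorical"))
}

#' Parameter vector for a model spec
#'
#' Assembles the named parameter vector `ofv()` and `fit_popmodel()`
#' work with: `theta_cl`, `theta_v`, one `theta_<name>` per covariate,
#' `omega2_*` for each random effect and `sigma2_1` (plus `sigma2_2`
#' for combined error) — variability terms on the variance scale.
#'
#' @param spec a [model_spec()].
#' @param fx,var,err optional parameter objects supplying values
#'   (`var`/`err` honouring their own scale convention); defaults give
#'   the published final-model estimates for `final_model_spec()`.
#' @return named numeric vector.
#' @export
params_for <- function(spec, fx = fixed_effects(),
                       var = variability_params(), err = residual_error()) {
  p <- c(theta_cl = fx$theta_cl, theta_v = fx$theta_v)
  for (nm in names(spec$covariates)) {
    val <- if (toupper(nm) == "OXC") fx$theta_oxc
           else if (spec$covariates[[nm]] == "categorical") 1 else 0
    p[paste0("theta_", tolower(nm))] <- val
  }
  o2 <- .omega2(var)
  if ("cl" %in% spec$eta) p["omega2_cl"] <- o2$cl
  if ("v" %in% spec$eta)  p["omega2_v"] <- if (is.null(o2$v)) 0.05 else o2$v
  s2 <- .sigma2(err)
  p["sigma2_1"] <- s2$s1
  if (spec$error == "combined") p["sigma2_2"] <- if (is.null(s2$s2)) 0.1 else s2$s2
  p
}

# ---- Gauss-Hermite nodes (Golub-Welsch) -------------------------------

# nodes x_k and weights w_k for integral f(x) e^{-x^2} dx
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# ---- objective construction ------------------------------------------

# Precompiles dataset-dependent structure: returns closures evaluating
# the OFV and the conditional eta modes for a natural-scale parameter
# vector.
.make_objfun <- function(data, spec, nagq = 9L) {
  obs <- .obs_table(data)
  ids <- unique(obs$id)
  sidx <- match(obs$id, ids)
  n_sub <- length(ids)
  n_obs <- nrow(obs)
  d <- length(spec$eta)
  has_cl <- "cl" %in% spec$eta
  has_v <- "v" %in% spec$eta

  # covariate design: values per observation and per-covariate medians
  cov_cols <- list()
  for (nm in names(spec$covariates)) {
    col <- tolower(nm)
    if (is.null(obs[[col]])) stop("covariate column not in data: ", nm)
    x <- obs[[col]]
    if (any(is.na(x))) stop("missing values in covariate ", nm)
    if (spec$covariates[[nm]] == "continuous") {
      med <- stats::median(x[!duplicated(obs$id)])
      if (med <= 0) stop("continuous covariate ", nm, " needs a positive median")
      cov_cols[[nm]] <- list(type = "continuous", x = x, med = med)
    } else {
      if (!all(x %in% c(0, 1))) stop("categorical covariate ", nm, " must be 0/1")
      cov_cols[[nm]] <- list(type = "categorical", x = x)
    }
  }

  wt_cl <- (obs$wt / spec$w_std)^spec$power_cl
  wt_v <- (obs$wt / spec$w_std)^spec$power_v
  gh <- gauss_hermite(if (d == 1) nagq else 1L)

  # typical values per observation for a parameter vector
  tv <- function(p) {
    tvcl <- p[["theta_cl"]] * wt_cl
    for (nm in names(cov_cols)) {
      cc <- cov_cols[[nm]]
      th <- p[[paste0("theta_", tolower(nm))]]
      tvcl <- tvcl * if (cc$type == "categorical") th^cc$x
                     else (cc$x / cc$med)^th
    }
    list(cl = tvcl, v = p[["theta_v"]] * wt_v)
  }

  s2_of <- function(p) {
    list(kind = spec$error, s1 = p[["sigma2_1"]],
         s2 = if (spec$error == "combined") p[["sigma2_2"]] else NULL)
  }

  # model machinery for a parameter vector: predictions, per-subject
  # -2 log joint density (observations + eta prior), its analytic eta
  # gradient, and the Gauss-Newton (FOCE-style) Hessian -- positive
  # definite by construction, residual variance at the conditional
  # prediction ("with interaction")
  make_model <- function(p) {
    tvs <- tv(p)
    s2 <- s2_of(p)
    o2 <- c(if (has_cl) p[["omega2_cl"]], if (has_v) p[["omega2_v"]])
    o2 <- pmax(o2, 1e-10)
    feval <- function(eta) {
      cl <- tvs$cl; v <- tvs$v; k <- 1
      if (has_cl) { cl <- cl * exp(eta[sidx, k]); k <- k + 1 }
      if (has_v)  v <- v * exp(eta[sidx, k])
      trough_steady_state(cl, v, obs$amt, obs$ii, ka = spec$ka)
    }
    lof <- function(eta, f = feval(eta)) {
      rv <- .res_var(f, s2)
      if (any(!is.finite(f)) || any(rv <= 0)) return(rep(Inf, n_sub))
      term <- log(2 * pi * rv) + (obs$dv - f)^2 / rv
      li <- rowsum(term, sidx, reorder = TRUE)[, 1]
      for (k in seq_len(d)) li <- li + log(2 * pi * o2[k]) + eta[, k]^2 / o2[k]
      li
    }
    fgrad <- function(eta, h = 1e-5) {
      G <- matrix(0, n_obs, d)
      for (k in seq_len(d)) {
        ek <- matrix(0, n_sub, d); ek[, k] <- h
        G[, k] <- (feval(eta + ek) - feval(eta - ek)) / (2 * h)
      }
      G
    }
    glh <- function(eta, f = feval(eta), G = fgrad(eta)) {
      rv <- .res_var(f, s2)
      r <- obs$dv - f
      drv_df <- switch(s2$kind, additive = 0,
                       proportional = 2 * s2$s1 * f,
                       combined = 2 * s2$s1 * f)
      grad <- matrix(0, n_sub, d)
      H <- array(0, c(n_sub, d, d))
      for (k in seq_len(d)) {
        dterm <- drv_df * G[, k] * (1 / rv - r^2 / rv^2) - 2 * r * G[, k] / rv
        grad[, k] <- rowsum(dterm, sidx, reorder = TRUE)[, 1] +
          2 * eta[, k] / o2[k]
        for (l in seq_len(k)) {
          Hkl <- rowsum(2 * G[, k] * G[, l] / rv, sidx, reorder = TRUE)[, 1]
          if (l == k) Hkl <- Hkl + 2 / o2[k]
          H[, k, l] <- H[, l, k] <- Hkl
        }
      }
      list(grad = grad, H = H)
    }
    list(feval = feval, lof = lof, fgrad = fgrad, glh = glh, o2 = o2, s2 = s2)
  }

  # vectorized Newton for the conditional modes (tolerance 1e-8 on eta):
  # analytic gradient, Gauss-Newton Hessian, per-subject backtracking
  inner_mode <- function(mdl) {
    eta <- matrix(0, n_sub, d)
    l0 <- mdl$lof(eta)
    for (iter in 1:80) {
      gh_ <- mdl$glh(eta)
      g <- gh_$grad; H <- gh_$H
      if (d == 1) {
        step <- matrix(-g[, 1] / H[, 1, 1], ncol = 1)
      } else {
        det <- H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2
        step <- cbind(-( H[, 2, 2] * g[, 1] - H[, 1, 2] * g[, 2]) / det,
                      -(-H[, 1, 2] * g[, 1] + H[, 1, 1] * g[, 2]) / det)
      }
      step <- pmin(pmax(step, -2), 2)
      t <- rep(1, n_sub)
      done <- rep(FALSE, n_sub)
      accepted <- l0
      eta_new <- eta
      for (ls in 1:10) {
        cand <- eta + step * t
        lc <- mdl$lof(cand)
        better <- !done & lc <= accepted + 1e-12
        eta_new[better, ] <- cand[better, , drop = FALSE]
        accepted[better] <- lc[better]
        done <- done | better
        if (all(done)) break
        t[!done] <- t[!done] / 2
      }
      moved <- max(abs(eta_new - eta))
      eta <- eta_new
      l0 <- accepted
      if (moved < 1e-8) break
    }
    list(eta = eta, l = l0)
  }

  # -2 log marginal likelihood
  fn <- function(p) {
    if (any(!is.finite(p))) return(Inf)
    o2 <- c(if (has_cl) p[["omega2_cl"]], if (has_v) p[["omega2_v"]])
    if (p[["theta_cl"]] <= 0 || p[["theta_v"]] <= 0 ||
        p[["sigma2_1"]] <= 0 || any(o2 < 0)) return(Inf)
    # degenerate variance: pure fixed-effects deviance at eta = 0
    if (all(o2 < 1e-12)) {
      tvs <- tv(p); s2 <- s2_of(p)
      f <- trough_steady_state(tvs$cl, tvs$v, obs$amt, obs$ii, ka = spec$ka)
      rv <- .res_var(f, s2)
      if (any(!is.finite(f)) || any(rv <= 0)) return(Inf)
      return(sum(log(2 * pi * rv) + (obs$dv - f)^2 / rv))
    }
    mdl <- make_model(p)
    mode <- inner_mode(mdl)
    eta <- mode$eta
    if (any(!is.finite(mode$l))) return(Inf)
    H <- mdl$glh(eta)$H
    if (d == 1) {
      H1 <- H[, 1, 1]
      if (length(gh$nodes) == 1) {
        ofv_i <- mode$l - log(2 * pi) + log(H1 / 2)
      } else {
        sig <- 1 / sqrt(H1 / 2) # scale from the curvature of l/2
        K <- length(gh$nodes)
        expo <- matrix(0, n_sub, K)
        for (k in seq_len(K))
          expo[, k] <- -mdl$lof(eta + sqrt(2) * sig * gh$nodes[k]) / 2 +
            log(gh$weights[k]) + gh$nodes[k]^2
        m <- apply(expo, 1, max)
        logL <- log(sqrt(2) * sig) + m + log(rowSums(exp(expo - m)))
        ofv_i <- -2 * logL
      }
    } else {
      det <- H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2
      ofv_i <- mode$l - d * log(2 * pi) + log(det / 2^d)
    }
    if (any(!is.finite(ofv_i))) return(Inf)
    sum(ofv_i)
  }

  ebe <- function(p) {
    o2 <- c(if (has_cl) p[["omega2_cl"]], if (has_v) p[["omega2_v"]])
    if (all(o2 < 1e-12)) {
      eta <- matrix(0, n_sub, d)
    } else {
      eta <- inner_mode(make_model(p))$eta
    }
    colnames(eta) <- paste0("eta_", spec$eta)
    data.frame(id = ids, eta)
  }

  list(fn = fn, ebe = ebe, obs = obs, ids = ids, sidx = sidx,
       n_sub = n_sub, n_obs = n_obs, tv = tv, s2_of = s2_of)
}

#' Objective function value (-2 log marginal likelihood)
#'
#' Evaluates the approximate marginal -2 log-likelihood of the
#' mixed-effects trough model, summed over subjects.  Each subject's
#' integral over the random effects is approximated by adaptive
#' Gauss-Hermite quadrature centered at the conditional mode (`nagq`
#' nodes; 1 node = Laplace) for a single random effect, and by the
#' Laplace approximation for two.  With all variances at zero the OFV
#' reduces to the fixed-effects weighted least-squares deviance.
#' Deterministic for fixed inputs; invariant to row and subject order.
#'
#' @param data a `tdm_data` dataset.
#' @param spec a [model_spec()].
#' @param params named parameter vector as produced by [params_for()].
#' @param nagq quadrature nodes for a single random effect (default 9).
#' @return the OFV (scalar; `Inf` if any prediction is non-finite).
#' @export
ofv <- function(data, spec = final_model_spec(),
                params = params_for(spec), nagq = 9L) {
  .make_objfun(validate_tdm(data), spec, nagq = nagq)$fn(params)
}
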