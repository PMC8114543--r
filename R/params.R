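#' Fixed-effect (typical-value) parameters of the covariate model
#'
#' Container for the population fixed effects of the final sirolimus model:
#' typical apparent clearance and volume at the 70 kg reference weight,
#' the oxcarbazepine clearance multiplier, the fixed allometric exponents
#' (0.75 for CL/F, 1 for V/F) and the fixed first-order absorption rate
#' constant.  Defaults are the published final-model estimates.
#'
#' @param theta_cl typical CL/F (L/h) at the reference weight.
#' @param theta_v typical V/F (L) at the reference weight.
#' @param theta_oxc multiplicative effect of oxcarbazepine comedication on
#'   CL/F (dimensionless, > 0).
#' @param power_cl,power_v allometric exponents for clearance and volume.
#' @param w_std reference weight (kg).
#' @param ka_fixed first-order absorption rate constant (1/h), not estimated.
#' @return an object of class `fixed_effects`.
#' @examples
#' fx <- fixed_effects()
#' typical_clearance(70, oxc = 0, fx) # 8.59 L/h
#' @export
fixed_effects <- function(theta_cl = 8.59, theta_v = 294, theta_oxc = 1.16,
                          power_cl = 0.75, power_v = 1,
                          w_std = 70, ka_fixed = 0.485) {
  stopifnot(is.numeric(theta_cl), length(theta_cl) == 1L,
            is.numeric(theta_v), length(theta_v) == 1L)
  if (theta_cl <= 0 || theta_v <= 0 || theta_oxc <= 0)
    stop("theta_cl, theta_v and theta_oxc must be strictly positive")
  if (w_std <= 0) stop("w_std must be strictly positive")
  if (ka_fixed <= 0) stop("ka_fixed must be strictly positive")
  structure(list(theta_cl = theta_cl, theta_v = theta_v,
                 theta_oxc = theta_oxc,
                 power_cl = power_cl, power_v = power_v,
                 w_std = w_std, ka_fixed = ka_fixed),
            class = "fixed_effects")
}

#' @export
print.fixed_effects <- function(x, ...) {
  cat("Fixed effects (typical values at", x$w_std, "kg):\n")
  cat(sprintf("  CL/F %.4g L/h (allometric exponent %.3g)\n", x$theta_cl, x$power_cl))
  cat(sprintf("  V/F  %.4g L   (allometric exponent %.3g)\n", x$theta_v, x$power_v))
  cat(sprintf("  OXC multiplier on CL/F %.4g\n", x$theta_oxc))
  cat(sprintf("  Ka fixed at %.4g 1/h\n", x$ka_fixed))
  invisible(x)
}

#' Inter-individual variability parameters
#'
#' Lognormal inter-individual variability (IIV) terms.  The final model
#' carries a single random effect on CL/F; the IIV on V/F was estimated
#' near zero in the base model and dropped, so `omega_v = NULL` is the
#' default.  Values may be stored either as variances (the NONMEM
#' OMEGA reporting convention, default) or as standard deviations; the
#' `scale` field records which, and [as_variance()] canonicalizes.
#'
#' @param omega_cl IIV term for CL/F (variance or SD per `scale`).
#' @param omega_v IIV term for V/F, or `NULL` when dropped.
#' @param scale `"variance"` or `"sd"`: how `omega_*` values are stored.
#' @return an object of class `variability_params`.
#' @export
variability_params <- function(omega_cl = 0.175, omega_v = NULL,
                               scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  if (omega_cl < 0) stop("omega_cl must be non-negative")
  if (!is.null(omega_v) && omega_v < 0) stop("omega_v must be non-negative")
  structure(list(omega_cl = omega_cl, omega_v = omega_v, scale = scale),
            class = "variability_params")
}

#' Residual (within-subject) error model
#'
#' One of the three standard residual-error laws for an observed
#' concentration O given the model prediction P:
#' additive `O = P + e1`, proportional `O = P(1 + e1)`, or combined
#' `O = P(1 + e1) + e2`, each `e` a zero-mean normal deviate.  The final
#' sirolimus model is additive with sigma1 = 1.913 (variance scale).
#'
#' @param kind `"additive"`, `"proportional"` or `"combined"`.
#' @param sigma1 first error term (variance or SD per `scale`).
#' @param sigma2 second error term, required (and only allowed) for
#'   `kind = "combined"`.
#' @param scale `"variance"` or `"sd"`.
#' @return an object of class `residual_error`.
#' @export
residual_error <- function(kind = c("additive", "proportional", "combined"),
                           sigma1 = 1.913, sigma2 = NULL,
                           scale = c("variance", "sd")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (sigma1 < 0) stop("sigma1 must be non-negative")
  if (kind == "combined") {
    if (is.null(sigma2)) stop("combined error requires sigma2")
    if (sigma2 < 0) stop("sigma2 must be non-negative")
  } else if (!is.null(sigma2)) {
    stop("sigma2 is only meaningful for the combined error model")
  }
  structure(list(kind = kind, sigma1 = sigma1, sigma2 = sigma2, scale = scale),
            class = "residual_error")
}

#' Convert a variability or error term to the variance scale
#'
#' @param x non-negative numeric value(s).
#' @param scale `"variance"` (returned as-is) or `"sd"` (squared).
#' @return value(s) on the variance scale.
#' @export
as_variance <- function(x, scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  if (any(x < 0)) stop("variability terms must be non-negative")
  if (scale == "sd") x^2 else x
}

# internal: variance-scale omegas/sigmas from the S3 containers
.omega2 <- function(var) {
  list(cl = as_variance(var$omega_cl, var$scale),
       v  = if (is.null(var$omega_v)) NULL else as_variance(var$omega_v, var$scale))
}

.sigma2 <- function(err) {
  list(kind = err$kind,
       s1 = as_variance(err$sigma1, err$scale),
       s2 = if (is.null(err$sigma2)) NULL else as_variance(err$sigma2, err$scale))
}
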