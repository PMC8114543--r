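# Structural one-compartment oral model with first-order absorption and
# elimination.  All parameters are apparent (CL/F, V/F); doses in mg,
# volumes in L, times in h, concentrations in ng/ml.

# The single mg/L -> ng/ml conversion used anywhere in the package.
MGL_TO_NGML <- 1000

# relative |ka - ke| below which the flip-flop limit form is used
.KA_KE_TOL <- 1e-9

#' Typical apparent clearance from the final covariate model
#'
#' CL/F = theta_cl x (weight / w_std)^0.75 x theta_oxc^OXC: allometric
#' weight scaling with a fixed 3/4 exponent and a multiplicative
#' oxcarbazepine comedication effect.
#'
#' @param weight body weight in kg (vectorized, > 0).
#' @param oxc oxcarbazepine comedication indicator, 0 or 1 (vectorized).
#' @param fx a [fixed_effects()] object.
#' @return typical CL/F in L/h.
#' @examples
#' typical_clearance(70, 0)          # 8.59
#' typical_clearance(70, 1) / typical_clearance(70, 0) # 1.16
#' @export
typical_clearance <- function(weight, oxc = 0, fx = fixed_effects()) {
  if (any(weight <= 0)) stop("weight must be strictly positive")
  if (!all(oxc %in% c(0, 1))) stop("oxc must be a 0/1 indicator")
  fx$theta_cl * (weight / fx$w_std)^fx$power_cl * fx$theta_oxc^oxc
}

#' Typical apparent volume of distribution from the final model
#'
#' V/F = theta_v x (weight / w_std): linear (exponent 1) allometry.
#'
#' @inheritParams typical_clearance
#' @return typical V/F in L.
#' @examples
#' typical_volume(70) # 294
#' @export
typical_volume <- function(weight, fx = fixed_effects()) {
  if (any(weight <= 0)) stop("weight must be strictly positive")
  fx$theta_v * (weight / fx$w_std)^fx$power_v
}

# accumulation kernel A(x) = exp(-x * tau) / (1 - exp(-x * tau))
.accum <- function(x, tau) {
  e <- exp(-x * tau)
  e / (1 - e)
}

#' Steady-state trough concentration for repeated oral dosing
#'
#' Closed-form trough (concentration at the end of the dosing interval)
#' at steady state for a one-compartment model with first-order
#' absorption, dose `dose_mg` every `interval` hours:
#' \deqn{C(\tau) = \frac{D k_a}{V (k_a - k_e)}
#'   \left[\frac{e^{-k_e\tau}}{1-e^{-k_e\tau}} -
#'         \frac{e^{-k_a\tau}}{1-e^{-k_a\tau}}\right] \times 1000}
#' with \eqn{k_e = CL/V}; the factor 1000 converts mg/L to ng/ml.
#' When \eqn{k_a \approx k_e} the analytic flip-flop limit
#' \eqn{D k_a \tau e^{-k_a\tau} / (V (1-e^{-k_a\tau})^2)} is used.
#'
#' All arguments are vectorized with the usual recycling.
#'
#' @param cl apparent clearance CL/F (L/h, > 0).
#' @param v apparent volume V/F (L, > 0).
#' @param dose_mg dose per administration (mg, >= 0).
#' @param interval dosing interval tau (h, > 0).
#' @param ka absorption rate constant (1/h).
#' @return steady-state trough concentration(s) in ng/ml.
#' @examples
#' trough_steady_state(8.59, 294, dose_mg = 2.1, interval = 24) # ~7.48
#' @export
trough_steady_state <- function(cl, v, dose_mg, interval, ka = 0.485) {
  if (any(cl <= 0) || any(v <= 0)) stop("cl and v must be strictly positive")
  if (any(dose_mg < 0)) stop("dose_mg must be non-negative")
  if (any(interval <= 0)) stop("interval must be strictly positive")
  n <- max(length(cl), length(v), length(dose_mg), length(interval))
  cl <- rep_len(cl, n); v <- rep_len(v, n)
  dose_mg <- rep_len(dose_mg, n); tau <- rep_len(interval, n)
  ke <- cl / v
  degen <- abs(ka - ke) / ka < .KA_KE_TOL
  out <- numeric(n)
  if (any(!degen)) {
    i <- !degen
    out[i] <- (dose_mg[i] * ka) / (v[i] * (ka - ke[i])) *
      (.accum(ke[i], tau[i]) - .accum(ka, tau[i]))
  }
  if (any(degen)) {
    i <- degen
    e <- exp(-ka * tau[i])
    out[i] <- dose_mg[i] * ka * tau[i] * e / (v[i] * (1 - e)^2)
  }
  out * MGL_TO_NGML
}

# single-dose concentration (ng/ml) at time s >= 0 after one oral dose
.conc_single <- function(cl, v, dose_mg, s, ka) {
  ke <- cl / v
  if (abs(ka - ke) / ka < .KA_KE_TOL) {
    dose_mg * ka * s * exp(-ka * s) / v * MGL_TO_NGML
  } else {
    (dose_mg * ka) / (v * (ka - ke)) * (exp(-ke * s) - exp(-ka * s)) * MGL_TO_NGML
  }
}

#' Concentration-time profile under repeated dosing
#'
#' Superposition of single-dose one-compartment curves for doses given
#' every `interval` hours starting at time 0.  At times `k * interval`
#' with large `k` the value converges to [trough_steady_state()].
#'
#' @inheritParams trough_steady_state
#' @param times non-negative, sorted observation times (h).
#' @param n_doses number of administrations; defaults to enough doses to
#'   cover `max(times)`.
#' @return concentrations (ng/ml) at `times`.
#' @export
concentration_profile <- function(cl, v, dose_mg, interval, times,
                                  ka = 0.485, n_doses = NULL) {
  stopifnot(length(cl) == 1L, length(v) == 1L, length(dose_mg) == 1L)
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  if (is.null(n_doses)) n_doses <- floor(max(times) / interval) + 1L
  dose_times <- (seq_len(n_doses) - 1L) * interval
  vapply(times, function(t) {
    s <- t - dose_times
    s <- s[s >= 0]
    if (!length(s)) return(0)
    sum(.conc_single(cl, v, dose_mg, s, ka))
  }, numeric(1))
}
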