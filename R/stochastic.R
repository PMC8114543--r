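# Random-effects layer: lognormal inter-individual variability and the
# three residual-error laws.

#' Derive a reproducible substream seed from a master seed and a tag
#'
#' Deterministic seed derivation so that every stage / scenario of a run
#' draws from its own reproducible stream.  The tag (e.g. `"pta:oxc1:qd"`)
#' is folded into the master seed by a small polynomial hash modulo
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param tag character scenario / stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), length(tag) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Draw individual parameters under lognormal inter-individual variability
#'
#' Realizes per-subject parameters `CL_i = TV(CL) x exp(eta_cl)` (and
#' `V_i = TV(V) x exp(eta_v)` when an IIV term on volume is present;
#' in the final model volume carries no random effect and is typical).
#' `eta ~ Normal(0, omega^2)` under the declared scale convention.
#'
#' @param weight,oxc subject covariates (vectorized; recycled to the
#'   longer of the two or `n`).
#' @param fx [fixed_effects()].
#' @param var [variability_params()].
#' @param n number of individuals to draw (defaults to the covariate length).
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return a data.frame with columns `weight`, `oxc`, `eta_cl`, `eta_v`,
#'   `cl`, `v`.
#' @export
sample_individuals <- function(weight, oxc = 0, fx = fixed_effects(),
                               var = variability_params(), n = NULL,
                               seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (is.null(n)) n <- max(length(weight), length(oxc))
  weight <- rep_len(weight, n); oxc <- rep_len(oxc, n)
  o2 <- .omega2(var)
  eta_cl <- if (o2$cl > 0) stats::rnorm(n, 0, sqrt(o2$cl)) else numeric(n)
  eta_v <- if (!is.null(o2$v) && o2$v > 0) stats::rnorm(n, 0, sqrt(o2$v)) else numeric(n)
  data.frame(weight = weight, oxc = oxc,
             eta_cl = eta_cl, eta_v = eta_v,
             cl = typical_clearance(weight, oxc, fx) * exp(eta_cl),
             v = typical_volume(weight, fx) * exp(eta_v))
}

#' Apply a residual-error model to model predictions
#'
#' Turns noiseless predictions P into simulated observations O under the
#' selected law: additive `O = P + e1`, proportional `O = P(1 + e1)`,
#' or combined `O = P(1 + e1) + e2`.  Negative draws (possible under
#' additive error) are returned as-is; truncation is a reporting-time
#' policy, not a simulation-time one.
#'
#' @param pred predicted concentrations (ng/ml, >= 0).
#' @param err [residual_error()].
#' @param seed optional integer seed (caller RNG state preserved).
#' @return simulated observations, same length as `pred`.
#' @export
apply_residual_error <- function(pred, err = residual_error(), seed = NULL) {
  if (any(pred < 0)) stop("pred must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  s2 <- .sigma2(err)
  n <- length(pred)
  switch(s2$kind,
    additive = pred + stats::rnorm(n, 0, sqrt(s2$s1)),
    proportional = pred * (1 + stats::rnorm(n, 0, sqrt(s2$s1))),
    combined = pred * (1 + stats::rnorm(n, 0, sqrt(s2$s1))) +
      stats::rnorm(n, 0, sqrt(s2$s2)))
}

# residual variance of an observation given its prediction, on the
# variance scale; used by the likelihood and the weighted residuals
.res_var <- function(pred, s2) {
  switch(s2$kind,
    additive = rep_len(s2$s1, length(pred)),
    proportional = s2$s1 * pred^2,
    combined = s2$s1 * pred^2 + s2$s2)
}
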