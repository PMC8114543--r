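# Flat key/value parameter files (YAML) carrying the fixed effects,
# variability and residual-error settings.

#' Read / write model parameters as a flat YAML file
#'
#' The file holds one key per parameter (`theta_cl`, `theta_v`,
#' `theta_oxc`, `power_cl`, `power_v`, `w_std`, `ka_fixed`, `omega_cl`,
#' optional `omega_v`, `error_kind`, `sigma1`, optional `sigma2`,
#' `scale`).  Missing keys take the package defaults — the reported
#' final-model estimates.  A ready-made file ships at
#' `system.file("extdata", "final_model_params.yaml", package = "siropop")`.
#'
#' @param path file path.
#' @return `read_param_config()`: list with `fx`, `var`, `err`.
#' @export
read_param_config <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path)
  y <- yaml::read_yaml(path)
  take <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  scale <- take("scale", "variance")
  fx <- fixed_effects(theta_cl = take("theta_cl", 8.59),
                      theta_v = take("theta_v", 294),
                      theta_oxc = take("theta_oxc", 1.16),
                      power_cl = take("power_cl", 0.75),
                      power_v = take("power_v", 1),
                      w_std = take("w_std", 70),
                      ka_fixed = take("ka_fixed", 0.485))
  var <- variability_params(omega_cl = take("omega_cl", 0.175),
                            omega_v = y[["omega_v"]], scale = scale)
  err <- residual_error(kind = take("error_kind", "additive"),
                        sigma1 = take("sigma1", 1.913),
                        sigma2 = y[["sigma2"]], scale = scale)
  list(fx = fx, var = var, err = err)
}

#' @rdname read_param_config
#' @param fx,var,err parameter objects to serialize.
#' @export
write_param_config <- function(path, fx = fixed_effects(),
                               var = variability_params(),
                               err = residual_error()) {
  if (var$scale != err$scale)
    stop("variability and error models use different scale conventions")
  y <- list(theta_cl = fx$theta_cl, theta_v = fx$theta_v,
            theta_oxc = fx$theta_oxc, power_cl = fx$power_cl,
            power_v = fx$power_v, w_std = fx$w_std, ka_fixed = fx$ka_fixed,
            omega_cl = var$omega_cl, omega_v = var$omega_v,
            error_kind = err$kind, sigma1 = err$sigma1, sigma2 = err$sigma2,
            scale = var$scale)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}
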