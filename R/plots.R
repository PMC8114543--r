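# Publication-style diagnostic plots (base graphics).

#' Goodness-of-fit plot quartet
#'
#' Observations vs population predictions, observations vs individual
#' predictions, |iWRES| vs individual predictions, and weighted
#' residuals vs time.
#'
#' @param gof output of [gof_diagnostics()].
#' @return invisibly, `gof`.
#' @export
plot_gof <- function(gof) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  lim <- range(c(gof$dv, gof$pred, gof$ipred))
  plot(gof$pred, gof$dv, xlab = "Population prediction (ng/ml)",
       ylab = "Observation (ng/ml)", xlim = lim, ylim = lim)
  graphics::abline(0, 1, lty = 2)
  plot(gof$ipred, gof$dv, xlab = "Individual prediction (ng/ml)",
       ylab = "Observation (ng/ml)", xlim = lim, ylim = lim)
  graphics::abline(0, 1, lty = 2)
  plot(gof$ipred, abs(gof$iwres), xlab = "Individual prediction (ng/ml)",
       ylab = "|iWRES|")
  plot(gof$time, gof$wres, xlab = "Time (h)", ylab = "Weighted residual")
  graphics::abline(h = 0, lty = 2)
  invisible(gof)
}

#' Weighted-residual distribution plots (density and normal Q-Q)
#' @param gof output of [gof_diagnostics()].
#' @return invisibly, `gof`.
#' @export
plot_wres_distribution <- function(gof) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(stats::density(gof$wres), main = "", xlab = "Weighted residual")
  graphics::curve(stats::dnorm(x), add = TRUE, lty = 2)
  stats::qqnorm(gof$wres, main = "")
  stats::qqline(gof$wres, lty = 2)
  invisible(gof)
}

#' Visual-predictive-check plot
#' @param x output of [vpc()].
#' @return invisibly, `x`.
#' @export
plot_vpc <- function(x) {
  b <- x$bins
  mid <- seq_len(nrow(b))
  ylim <- range(c(b$obs_lo, b$obs_hi, b$sim_lo, b$sim_hi))
  plot(mid, b$obs_med, type = "b", pch = 16, ylim = ylim, xaxt = "n",
       xlab = "Weight bin", ylab = "Prediction-corrected concentration (ng/ml)")
  graphics::axis(1, at = mid, labels = b$bin)
  graphics::lines(mid, b$obs_lo, type = "b", lty = 2)
  graphics::lines(mid, b$obs_hi, type = "b", lty = 2)
  graphics::polygon(c(mid, rev(mid)), c(b$sim_lo, rev(b$sim_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(mid, b$sim_med, col = "steelblue")
  invisible(x)
}

#' Probability-of-target-attainment curves
#'
#' PTA against dose, one curve per weight.
#'
#' @param grid a `pta_grid` from [simulate_pta()].
#' @return invisibly, `grid`.
#' @export
plot_pta <- function(grid) {
  ws <- sort(unique(grid$weight))
  cols <- grDevices::hcl.colors(length(ws), "viridis")
  plot(NA, xlim = range(grid$dose), ylim = c(0, max(grid$pta) * 1.1),
       xlab = "Dose (mg/kg/day)", ylab = "Probability of target attainment")
  for (i in seq_along(ws)) {
    g <- grid[grid$weight == ws[i], ]
    graphics::lines(g$dose, g$pta, col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("topright", legend = paste(ws, "kg"), col = cols,
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(grid)
}
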