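#' Plot a steady-state overlap phase grid
#'
#' Heatmap of mean steady-state overlap over the (alpha, m0) grid.
#'
#' @param x a `phase_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.phase_grid <- function(x, ...) {
  graphics::image(x$alphas, x$m0s, x$mss_mean,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = expression(alpha), ylab = expression(m(0)),
                  main = sprintf("steady-state overlap (gamma = %s)",
                                 format(x$gamma)), ...)
  invisible(x)
}

#' Plot overlap trajectories
#'
#' @param x a `trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$m, type = "l", lty = 1,
                    xlab = "t", ylab = "m(t)", ylim = c(-1, 1), ...)
  invisible(x)
}

#' Plot a two-pattern flow field in (m+, m-) coordinates
#'
#' Endpoints (solid) and displacement segments from each initial condition,
#' in the sum/difference overlap coordinates.
#'
#' @param x a `flow_field`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flow_field <- function(x, ...) {
  s0 <- to_sum_diff(x$results[, c("m1_0", "m2_0")])
  sT <- to_sum_diff(x$results[, c("m1_T", "m2_T")])
  graphics::plot(s0, xlim = c(-2, 2), ylim = c(-2, 2), pch = 1, col = "grey60",
                 xlab = expression(m["+"]), ylab = expression(m["-"]), ...)
  graphics::segments(s0[, 1], s0[, 2], sT[, 1], sT[, 2], col = "grey80")
  graphics::points(sT, pch = 19, col = "navy")
  invisible(x)
}
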