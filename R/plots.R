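#' Plot a cross-calibration fit
#'
#' Scatter of Ba-133 against I-131 pseudo-ICFs with the fitted
#' setup-specific line (solid) and the emission-probability-ratio line
#' through the origin (dashed) for reference.
#'
#' @param x A [fit_cross_calibration()] result.
#' @param emission_ratio Ratio to draw as the dashed reference line
#'   (default the Ba-133/I-131 value).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crosscal_fit <- function(x, emission_ratio =
                                emission_probability_ratio(ba133(), i131())$ratio,
                              ...) {
  dat <- x$lm$model
  graphics::plot(dat$i131, dat$ba133,
                 xlab = "I-131 pseudo-ICF (cps/MBq)",
                 ylab = "Ba-133 pseudo-ICF (cps/MBq)",
                 pch = 19, ...)
  graphics::abline(x$offset, x$slope, lwd = 2)
  graphics::abline(0, emission_ratio, lty = 2)
  graphics::legend("topleft", bty = "n", lty = c(1, 2), lwd = c(2, 1),
                   legend = c(sprintf("fit: %.3g + %.3g x", x$offset, x$slope),
                              sprintf("emission ratio %.3f", emission_ratio)))
  invisible(x)
}

#' Plot a pseudo-recovery curve
#'
#' @param x A [fit_recovery_curve()] result.
#' @param volumes Optional data volumes to mark.
#' @param values Optional data values to mark.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::curve()] / [graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.recovery_fit <- function(x, volumes = NULL, values = NULL,
                              add = FALSE, ...) {
  v <- seq(max(1e-3, x$volume_range[1] / 2), x$volume_range[2] * 1.1,
           length.out = 200)
  if (!add) {
    graphics::plot(v, predict(x, v), type = "l",
                   xlab = "volume (mL)", ylab = "pseudo-ICF (cps/MBq)",
                   ylim = c(0, max(x$plateau, values) * 1.05), ...)
  } else {
    graphics::lines(v, predict(x, v), ...)
  }
  if (!is.null(volumes)) graphics::points(volumes, values, pch = 19)
  invisible(x)
}
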