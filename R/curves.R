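#' Time-attenuation curve
#'
#' A sampled time-enhancement function: either an arterial input function
#' (AIF, measured in the aorta) or a myocardial tissue curve (TAC). Values are
#' Hounsfield-unit enhancement above the pre-contrast baseline.
#'
#' @param times_s numeric, sample times in seconds, strictly increasing.
#' @param values numeric, HU enhancement at each time; same length as `times_s`.
#' @return An object of class `tac_curve`: a list with elements `times_s` and
#'   `values`.
#' @examples
#' cv <- tac_curve(0:10, c(0, 0, 1, 5, 12, 18, 16, 12, 9, 7, 5))
#' plot(cv)
#' @export
tac_curve <- function(times_s, values) {
  times_s <- as.numeric(times_s)
  values <- as.numeric(values)
  if (length(times_s) != length(values))
    stopf("times_s and values must have equal length")
  if (length(times_s) < 2L) stopf("a curve needs at least 2 samples")
  if (any(!is.finite(times_s)) || any(!is.finite(values)))
    stopf("curve samples must be finite")
  if (any(diff(times_s) <= 0)) stopf("times_s must be strictly increasing")
  structure(list(times_s = times_s, values = values), class = "tac_curve")
}

#' @export
print.tac_curve <- function(x, ...) {
  cat(sprintf("Time-attenuation curve: %d samples, t = [%.2f, %.2f] s, peak %.1f HU at %.1f s\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              max(x$values), x$times_s[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.tac_curve <- function(x, ..., xlab = "time (s)", ylab = "enhancement (HU)",
                           type = "o", pch = 16, cex = 0.6) {
  graphics::plot(x$times_s, x$values, xlab = xlab, ylab = ylab,
                 type = type, pch = pch, cex = cex, ...)
  invisible(x)
}

#' Resample a curve onto a new time grid
#'
#' Linear interpolation; values before the first sample are 0 (pre-bolus),
#' values after the last sample hold the final value (no extrapolation beyond
#' the acquired window).
#'
#' @param curve a [tac_curve()].
#' @param times_s new sample times, strictly increasing.
#' @return a `tac_curve` on the new grid.
#' @export
resample_curve <- function(curve, times_s) {
  if (any(diff(times_s) <= 0)) stopf("times_s must be strictly increasing")
  v <- stats::approx(curve$times_s, curve$values, xout = times_s,
                     yleft = 0, yright = curve$values[length(curve$values)])$y
  tac_curve(times_s, v)
}

#' Numeric area under a curve
#' @param curve a [tac_curve()].
#' @return trapezoidal AUC (HU·s).
#' @export
curve_auc <- function(curve) trapz(curve$times_s, curve$values)
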