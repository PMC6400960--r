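#' Temporal gate axis of a time-resolved acquisition
#'
#' Defines the discrete time-gate grid of the single-pixel TCSPC acquisition:
#' `n_gates` bins of width `gate_width` nanoseconds starting at `origin`.
#' The default 256 gates x 40 ps span a 10.24 ns window, which samples the
#' 0.3-1.5 ns lifetimes of near-infrared dyes with a long tail.
#'
#' @param n_gates number of time gates (>= 2).
#' @param gate_width gate width in ns (> 0).
#' @param origin time of gate 0 in ns.
#' @return object of class `temporal_axis` with fields `n_gates`, `gate_width`,
#'   `origin` and the gate-time vector `t` (ns, gate left edges).
#' @export
temporal_axis <- function(n_gates = 256L, gate_width = 0.040, origin = 0) {
  assert_scalar_num(n_gates, "n_gates", lower = 2)
  assert_scalar_num(gate_width, "gate_width")
  if (gate_width <= 0) stop("`gate_width` must be positive")
  n_gates <- as.integer(n_gates)
  structure(list(
    n_gates = n_gates, gate_width = gate_width, origin = origin,
    t = origin + (seq_len(n_gates) - 1) * gate_width
  ), class = "temporal_axis")
}

#' @export
print.temporal_axis <- function(x, ...) {
  cat(sprintf("<temporal_axis> %d gates x %.4g ns = %.4g ns window (origin %.3g ns)\n",
              x$n_gates, x$gate_width, x$n_gates * x$gate_width, x$origin))
  invisible(x)
}

new_irf <- function(kernel, fwhm, t0) {
  if (any(kernel < 0)) stop("IRF kernel must be nonnegative")
  s <- sum(kernel)
  if (s <= 0) stop("IRF kernel must have positive mass")
  if (abs(s - 1) > 1e-9) kernel <- kernel / s
  structure(list(kernel = kernel, fwhm = fwhm, t0 = t0), class = "irf")
}

#' Gaussian instrument response function
#'
#' Discretizes a Gaussian temporal instrument response on the gate grid and
#' normalizes it to unit sum so convolution conserves photons. The default
#' (FWHM 0.2 ns, peak at 1.0 ns) stands in for a PMT-TCSPC response; a measured
#' IRF can be loaded with [read_irf()].
#'
#' @param axis a [temporal_axis()].
#' @param fwhm full width at half maximum, ns.
#' @param t0 peak position, ns.
#' @return object of class `irf` with unit-sum `kernel` (length `n_gates`).
#' @export
gaussian_irf <- function(axis, fwhm = 0.2, t0 = 1.0) {
  stopifnot(inherits(axis, "temporal_axis"))
  assert_scalar_num(fwhm, "fwhm"); assert_scalar_num(t0, "t0")
  if (fwhm <= 0) stop("`fwhm` must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k <- exp(-0.5 * ((axis$t - t0) / sigma)^2)
  new_irf(k, fwhm = fwhm, t0 = t0)
}

#' Delta (ideal) instrument response
#'
#' Unit impulse at gate 0; convolution with it is the identity.
#' @param axis a [temporal_axis()].
#' @return an `irf` object.
#' @export
delta_irf <- function(axis) {
  k <- numeric(axis$n_gates); k[1] <- 1
  new_irf(k, fwhm = 0, t0 = axis$origin)
}

#' Read an instrument response function from a two-column ASCII file
#'
#' Expects whitespace- or comma-separated `time_ns value` rows; values are
#' linearly interpolated onto the gate grid, clipped at zero and normalized
#' to unit sum.
#'
#' @param path file path.
#' @param axis a [temporal_axis()] to resample onto.
#' @return an `irf` object.
#' @export
read_irf <- function(path, axis) {
  stopifnot(inherits(axis, "temporal_axis"))
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("t", "v"), comment.char = "#")
  if (nrow(tab) < 2) stop("IRF file needs at least two rows")
  k <- stats::approx(tab$t, tab$v, xout = axis$t, yleft = 0, yright = 0)$y
  k[k < 0] <- 0
  peak <- axis$t[which.max(k)]
  half <- which(k >= max(k) / 2)
  fwhm <- if (length(half) > 1) diff(range(axis$t[half])) else axis$gate_width
  new_irf(k, fwhm = fwhm, t0 = peak)
}
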