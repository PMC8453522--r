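# Smoothing-spline detrending.
#
# The smoother is a discrete cubic smoothing spline (second-difference
# roughness penalty) whose smoothing constant is set from the desired
# frequency response: the interior transfer function is
#   H(omega) = 1 / (1 + lambda * (2 - 2*cos(omega))^2),
# so H = 0.5 at wavelength p years gives lambda = 1 / (16 * sin(pi/p)^4)
# (the Cook-Peters parameterization). Constant and linear series pass
# through unchanged.

ff_smooth <- function(y, wavelength) {
  n <- length(y)
  lambda <- 1 / (16 * sin(pi / wavelength)^4)
  D <- diff(diag(n), differences = 2)
  as.vector(solve(diag(n) + lambda * crossprod(D), y))
}

#' Detrend a ring-width series with a smoothing spline
#'
#' Fits a smoothing spline with a 50% frequency response at a wavelength of
#' two thirds of the series length (the standard flexible detrending choice
#' in dendrochronology) and returns the ratio index `width / spline`.
#'
#' @param widths Ring widths (mm), length >= 10, no internal NA.
#' @param wavelength Wavelength (years) at which the frequency response is
#'   0.5; default `ceiling(2 * n / 3)`.
#' @param tree_id Label used in diagnostics.
#' @return Unitless index series with attribute `spline` (the fitted curve).
#' @export
spline_detrend <- function(widths, wavelength = NULL, tree_id = "tree") {
  n <- length(widths)
  if (n < 10) stopf("series length %d < 10: too short to detrend", n)
  wavelength <- wavelength %||% ceiling(2 * n / 3)
  g <- ff_smooth(widths, wavelength)
  if (any(g <= 0))
    stopf("tree '%s': non-positive spline value during detrending", tree_id)
  structure(widths / g, spline = g)
}

#' Detrend every series of a ring-width data frame
#'
#' @param rwl Ring-width data frame (years x series).
#' @inheritParams spline_detrend
#' @return Data frame of ring-width indices with the same shape.
#' @export
detrend_rwl <- function(rwl, wavelength = NULL) {
  out <- rwl
  for (id in colnames(rwl)) {
    ok <- !is.na(rwl[[id]])
    out[ok, id] <- spline_detrend(rwl[[id]][ok], wavelength, tree_id = id)
  }
  out
}

#' Lag-k autocorrelation of a growth series
#'
#' Pearson correlation of a series with its k-year lagged copy.
#'
#' @param x Numeric series.
#' @param lag Lag in years (0 returns 1).
#' @return Correlation coefficient.
#' @export
autocorrelation <- function(x, lag = 1) {
  n <- length(x)
  if (n <= lag + 2) stopf("series too short for lag %d", lag)
  if (lag == 0) return(1)
  cor(x[seq_len(n - lag)], x[seq_len(n - lag) + lag])
}
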