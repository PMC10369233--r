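# Wavenumber axes, spectra, area normalization and CH2/CH3 band integration.

#' Default CH2 and CH3 integration windows (cm^-1)
#'
#' The methylene (CH2) stretch window spans 2832--2888 cm^-1 and the methyl
#' (CH3) window 2909--2967 cm^-1. The CH2/CH3 area ratio grows with saturated
#' fatty-acid chain length because internal CH2 groups scale with the chain
#' while the terminal CH3 group is fixed.
#' @format Numeric length-2 vectors `c(lo, hi)`.
#' @export
CH2_WINDOW <- c(2832, 2888)

#' @rdname CH2_WINDOW
#' @export
CH3_WINDOW <- c(2909, 2967)

.validate_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2)
    stop("wavenumber axis must be numeric with at least 2 points", call. = FALSE)
  if (any(!is.finite(wavenumber)) || any(wavenumber <= 0))
    stop("wavenumber axis must be finite and positive", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  invisible(wavenumber)
}

#' Construct an SRS spectrum
#'
#' A spectrum is an intensity profile (arbitrary SRS units) on a strictly
#' increasing wavenumber axis in cm^-1.
#'
#' @param wavenumber Strictly increasing numeric vector of wavenumbers (cm^-1).
#' @param intensity Non-negative numeric vector, same length as `wavenumber`.
#' @return An object of class `srs_spectrum`.
#' @export
srs_spectrum <- function(wavenumber, intensity) {
  .validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber))
    stop("intensity length must equal axis length", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity)),
            class = "srs_spectrum")
}

#' @export
print.srs_spectrum <- function(x, ...) {
  cat(sprintf("SRS spectrum: %d points, %.1f-%.1f cm^-1, area %.4g\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              trapz(x$wavenumber, x$intensity)))
  invisible(x)
}

#' Trapezoidal integral on a (possibly non-uniform) grid
#'
#' @param x Strictly increasing abscissae.
#' @param y Ordinates, same length as `x`.
#' @return The trapezoid-rule integral of `y` over `x`.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Integrate a spectrum over a wavenumber window
#'
#' Trapezoid rule on the native grid; window endpoints that fall between grid
#' points are included by linear interpolation, so the integral is exact for
#' piecewise-linear spectra.
#'
#' @param s An [srs_spectrum()].
#' @param window Numeric `c(lo, hi)` in cm^-1, inside the axis span.
#' @return Area under the curve over the window.
#' @export
auc_window <- function(s, window) {
  stopifnot(inherits(s, "srs_spectrum"), length(window) == 2, window[1] < window[2])
  w <- s$wavenumber
  if (window[1] < w[1] || window[2] > w[length(w)])
    stop(sprintf("window [%g, %g] outside axis span [%g, %g]",
                 window[1], window[2], w[1], w[length(w)]), call. = FALSE)
  inside <- w > window[1] & w < window[2]
  xs <- c(window[1], w[inside], window[2])
  ys <- c(stats::approx(w, s$intensity, xout = window[1])$y,
          s$intensity[inside],
          stats::approx(w, s$intensity, xout = window[2])$y)
  trapz(xs, ys)
}

#' Normalize a spectrum to unit trapezoidal area
#'
#' Pure-component references are put on a common scale before GC-MS weighting
#' by dividing out the trapezoidal area over the full axis; shape is preserved.
#' Idempotent: normalizing a unit-area spectrum returns it unchanged.
#'
#' @param s An [srs_spectrum()] with positive total area.
#' @return A unit-area `srs_spectrum`.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "srs_spectrum"))
  a <- trapz(s$wavenumber, s$intensity)
  if (!is.finite(a) || a <= 0)
    stop("cannot normalize: spectrum has non-positive area", call. = FALSE)
  srs_spectrum(s$wavenumber, s$intensity / a)
}

#' CH2/CH3 area-under-curve ratio of a spectrum
#'
#' Ratio of the trapezoidal AUC in the CH2 window to that in the CH3 window.
#' Invariant to global rescaling of the spectrum. Returns `NaN` (with a
#' warning) when the CH3 area is not meaningfully positive, leaving the
#' undefined-pixel policy to the caller.
#'
#' @param s An [srs_spectrum()] whose axis covers both windows.
#' @param cal Optional [chain_length_calibration()] supplying the windows;
#'   when `NULL` the defaults [CH2_WINDOW]/[CH3_WINDOW] are used.
#' @param eps CH3 areas at or below `eps` yield `NaN`.
#' @return A single numeric ratio.
#' @export
ch2_ch3_auc_ratio <- function(s, cal = NULL, eps = 1e-12) {
  win2 <- if (is.null(cal)) CH2_WINDOW else cal$ch2_window
  win3 <- if (is.null(cal)) CH3_WINDOW else cal$ch3_window
  a3 <- auc_window(s, win3)
  if (!is.finite(a3) || a3 <= eps) {
    warning("CH3 window area is ~0; ratio undefined", call. = FALSE)
    return(NaN)
  }
  auc_window(s, win2) / a3
}
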