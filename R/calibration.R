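# Chain-length calibration: chain length vs CH2/CH3 AUC ratio of saturated
# fatty-acid standards, fitted by ordinary least squares.

#' Construct a chain-length calibration
#'
#' Linear map from CH2/CH3 AUC ratio to saturated fatty-acid chain length,
#' with the integration windows it was built for.
#'
#' @param slope,intercept OLS coefficients (chain length = slope * ratio +
#'   intercept); `slope` must be positive.
#' @param r_squared Coefficient of determination of the fit.
#' @param ch2_window,ch3_window Integration windows (cm^-1), non-overlapping.
#' @return Object of class `chain_length_calibration`.
#' @export
chain_length_calibration <- function(slope, intercept, r_squared = NA_real_,
                                     ch2_window = CH2_WINDOW,
                                     ch3_window = CH3_WINDOW) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (max(ch2_window) > min(ch3_window) && max(ch3_window) > min(ch2_window))
    stop("CH2 and CH3 windows must not overlap", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared,
                 ch2_window = as.numeric(ch2_window),
                 ch3_window = as.numeric(ch3_window)),
            class = "chain_length_calibration")
}

#' @export
print.chain_length_calibration <- function(x, ...) {
  cat(sprintf("Chain-length calibration: n = %.4f * ratio + %.4f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  CH2 window %g-%g cm^-1, CH3 window %g-%g cm^-1\n",
              x$ch2_window[1], x$ch2_window[2], x$ch3_window[1], x$ch3_window[2]))
  invisible(x)
}

#' Fit the chain-length calibration from saturated standards
#'
#' The CH2/CH3 AUC ratio of saturated fatty acids scales approximately
#' linearly with chain length (internal CH2 groups grow with the chain, the
#' terminal CH3 is fixed). Chain length is regressed on the ratio by ordinary
#' least squares so the fit can be inverted per pixel by a single affine map.
#'
#' @param spectra List of standard [srs_spectrum()]s (replicates allowed).
#' @param chain_length Integer chain length of each standard.
#' @param ch2_window,ch3_window Integration windows (cm^-1).
#' @return A [chain_length_calibration()].
#' @export
fit_chain_length_calibration <- function(spectra, chain_length,
                                         ch2_window = CH2_WINDOW,
                                         ch3_window = CH3_WINDOW) {
  stopifnot(length(spectra) == length(chain_length))
  if (length(unique(chain_length)) < 3)
    stop("need standards at >= 3 distinct chain lengths", call. = FALSE)
  cal0 <- chain_length_calibration(1, 0, NA, ch2_window, ch3_window)
  ratio <- vapply(spectra, ch2_ch3_auc_ratio, 0, cal = cal0)
  if (any(!is.finite(ratio)))
    stop("undefined CH2/CH3 ratio among standards", call. = FALSE)
  if (stats::var(ratio) <= 0)
    stop("zero ratio variance; calibration underdetermined", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ratio), as.numeric(chain_length))
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  r2 <- 1 - sum(fit$residuals^2) / sum((chain_length - mean(chain_length))^2)
  chain_length_calibration(unname(slope), unname(intercept), r2,
                           ch2_window, ch3_window)
}

#' Predict chain length from a CH2/CH3 AUC ratio
#'
#' Applies the affine calibration. Predictions are continuous (a pixel holding
#' a mixture of chain lengths yields a non-integer average such as 14.9). By
#' default values are clipped to the span of the standards, carbons 6--20,
#' with the out-of-range positions reported in an `out_of_range` attribute.
#'
#' @param ratio Numeric vector of AUC ratios (NaN propagates to NA).
#' @param cal A [chain_length_calibration()].
#' @param clip Clip predictions to `range`? Default `TRUE`.
#' @param range Clip range, default `c(6, 20)`.
#' @return Numeric vector of predicted chain lengths.
#' @export
predict_chain_length <- function(ratio, cal, clip = TRUE, range = c(6, 20)) {
  stopifnot(inherits(cal, "chain_length_calibration"))
  n <- cal$slope * ratio + cal$intercept
  if (clip) {
    oor <- which(is.finite(n) & (n < range[1] | n > range[2]))
    n <- pmin(pmax(n, range[1]), range[2])
    if (length(oor)) attr(n, "out_of_range") <- oor
  }
  n
}
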