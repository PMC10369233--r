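# Chain-length maps and distributions, unsaturation ratios, and
# Jensen-Shannon comparison against GC-MS ground truth.

#' Per-pixel average saturated chain-length map
#'
#' Reconstructs the saturated-only stack from the chemical maps, computes
#' each pixel's CH2/CH3 AUC ratio, and applies the linear calibration.
#' Pixels whose total saturated signal does not exceed the threshold are
#' left `NA` (low-SNR ratio estimates fluctuate strongly). The map is
#' invariant to global rescaling of the input stack because the AUC ratio
#' is scale-free and the default threshold scales with the maps.
#'
#' @param maps A [unmix_stack()] result.
#' @param lib The [reference_library()] used for unmixing.
#' @param cal A [chain_length_calibration()].
#' @param threshold Minimum per-pixel saturated total (AUC-weighted map
#'   units). Default `NULL`: 5 x a robust noise estimate, the median
#'   absolute deviation of the saturated-total image (background pixels
#'   dominate typical scenes).
#' @param clip_range Predictions clipped to this span (standards range).
#' @return Nx x Ny matrix of predicted chain lengths (`NA` where undefined),
#'   with the threshold used in attribute `threshold`.
#' @export
chain_length_map <- function(maps, lib, cal, threshold = NULL,
                             clip_range = c(6, 20)) {
  stopifnot(inherits(maps, "chemical_maps"),
            inherits(cal, "chain_length_calibration"))
  sat <- maps$component[maps$category == "saturated"]
  if (length(sat) == 0) stop("no saturated components in maps", call. = FALSE)
  sat_stack <- reconstruct_component_stack(maps, lib, sat)
  d <- dim(maps$maps)
  sat_total <- matrix(.map_matrix(maps)[, match(sat, maps$component), drop = FALSE] %*%
                        maps$ref_auc[sat], d[1], d[2])
  if (is.null(threshold)) {
    threshold <- 5 * stats::mad(sat_total, center = stats::median(sat_total))
  }
  w <- sat_stack$wavenumber
  npix <- d[1] * d[2]
  M <- matrix(sat_stack$data, npix, length(w))
  a2 <- .window_weights(w, cal$ch2_window)
  a3 <- .window_weights(w, cal$ch3_window)
  auc2 <- as.vector(M %*% a2)
  auc3 <- as.vector(M %*% a3)
  ratio <- ifelse(auc3 > 0, auc2 / auc3, NaN)
  n <- predict_chain_length(ratio, cal, clip = TRUE, range = clip_range)
  n[!(sat_total > threshold) | !is.finite(ratio)] <- NA_real_
  out <- matrix(as.numeric(n), d[1], d[2])
  attr(out, "threshold") <- threshold
  out
}

# Quadrature weights such that sum(w * y) equals the trapezoidal integral of
# y over [lo, hi] with linear interpolation at the window endpoints.
.window_weights <- function(x, window) {
  n <- length(x)
  xs <- sort(unique(c(x, window)))
  xs <- xs[xs >= window[1] & xs <= window[2]]
  A <- vapply(seq_len(n), function(i) {
    y <- rep(0, n); y[i] <- 1
    ys <- stats::approx(x, y, xout = xs)$y
    trapz(xs, ys)
  }, 0)
  A
}

#' Bin a continuous chain-length prediction to an even carbon number
#'
#' Nearest even carbon; exact odd-integer midpoints round down (14.9 and
#' 15.0 both bin to C14, 15.1 bins to C16). `NA` propagates.
#'
#' @param value Numeric vector of predicted chain lengths.
#' @return Integer vector of even carbon numbers.
#' @export
bin_chain_length <- function(value) {
  out <- 2L * as.integer(ceiling((value - 1) / 2))
  out[!is.finite(value)] <- NA_integer_
  out
}

#' Saturated chain-length distribution from chemical maps
#'
#' Per-bin fractions of total saturated fatty-acid mass over a region.
#' The default `"mass"` route assigns each saturated component's
#' concentration mass (map sum times reference area) to its chain-length
#' bin. The alternative `"pixel"` route bins the per-pixel average
#' chain-length prediction, weighting each pixel by its saturated mass.
#' Mass outside the bin range is clipped into the terminal bins with a
#' warning. Fractions sum to 1.
#'
#' @param maps A [unmix_stack()] result.
#' @param region Optional logical/0-1 matrix selecting pixels (default all).
#' @param bins Even-carbon bin centers (default C8--C18, matching GC-MS
#'   reporting).
#' @param method `"mass"` (default) or `"pixel"`.
#' @param lib,cal,threshold Required for the `"pixel"` route: the library,
#'   calibration and threshold passed to [chain_length_map()].
#' @return Named numeric vector of fractions (class
#'   `chain_length_distribution`).
#' @export
chain_length_distribution <- function(maps, region = NULL,
                                      bins = seq(8L, 18L, 2L),
                                      method = c("mass", "pixel"),
                                      lib = NULL, cal = NULL, threshold = NULL) {
  stopifnot(inherits(maps, "chemical_maps"))
  method <- match.arg(method)
  d <- dim(maps$maps)
  sel <- if (is.null(region)) rep(TRUE, d[1] * d[2]) else {
    stopifnot(all(dim(region) == d[1:2]))
    as.vector(region) > 0
  }
  sat <- which(maps$category == "saturated")
  if (length(sat) == 0) stop("no saturated components in maps", call. = FALSE)
  mass <- numeric(0)
  at <- integer(0)
  if (method == "mass") {
    M <- .map_matrix(maps)[sel, sat, drop = FALSE]
    mass <- colSums(M) * maps$ref_auc[sat]
    at <- maps$chain_length[sat]
  } else {
    if (is.null(lib) || is.null(cal))
      stop("pixel route needs `lib` and `cal`", call. = FALSE)
    clm <- chain_length_map(maps, lib, cal, threshold = threshold)
    w <- matrix(.map_matrix(maps)[, sat, drop = FALSE] %*% maps$ref_auc[sat],
                d[1], d[2])
    ok <- sel & is.finite(as.vector(clm)) & as.vector(w) > 0
    at <- bin_chain_length(as.vector(clm)[ok])
    mass <- as.vector(w)[ok]
  }
  if (sum(mass) <= 0)
    stop("zero saturated mass in region; empty distribution", call. = FALSE)
  clipped <- pmin(pmax(at, min(bins)), max(bins))
  if (any(clipped != at & mass > 0))
    warning("saturated mass outside bin range clipped into terminal bins",
            call. = FALSE)
  p <- vapply(bins, function(b) sum(mass[clipped == b]), 0)
  p <- p / sum(p)
  names(p) <- paste0("C", bins)
  structure(p, class = "chain_length_distribution", bins = as.integer(bins))
}

#' Unsaturation ratio of a region
#'
#' Total unsaturated fatty-acid mass divided by total saturated mass, each
#' component's map sum weighted by its reference spectrum's area so the
#' ratio is a concentration-mass ratio even for GC-MS-scaled libraries.
#'
#' @param maps A [unmix_stack()] result with an unsaturated composite and
#'   at least one saturated component.
#' @param region Optional logical/0-1 matrix selecting pixels.
#' @return Non-negative scalar.
#' @export
unsaturation_ratio <- function(maps, region = NULL) {
  stopifnot(inherits(maps, "chemical_maps"))
  uns <- which(maps$category == "unsaturated")
  sat <- which(maps$category == "saturated")
  if (length(uns) == 0 || length(sat) == 0)
    stop("need an unsaturated composite and >= 1 saturated component",
         call. = FALSE)
  d <- dim(maps$maps)
  sel <- if (is.null(region)) rep(TRUE, d[1] * d[2]) else as.vector(region) > 0
  M <- .map_matrix(maps)[sel, , drop = FALSE]
  sat_mass <- sum(M[, sat, drop = FALSE] %*% maps$ref_auc[sat])
  if (sat_mass <= 0)
    stop("zero saturated mass in region; ratio undefined", call. = FALSE)
  uns_mass <- sum(M[, uns, drop = FALSE] %*% maps$ref_auc[uns])
  uns_mass / sat_mass
}

#' Jensen-Shannon divergence between two binned distributions
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`,
#' logarithms base 2, and `0 log 0 = 0`. Symmetric and bounded in [0, 1];
#' 0 iff the distributions are equal, 1 for disjoint supports.
#'
#' @param p,q Probability vectors over the same bins (named vectors or
#'   [chain_length_distribution()] objects); each must sum to 1.
#' @return Scalar divergence in [0, 1].
#' @export
js_divergence <- function(p, q) {
  p <- unclass(p); q <- unclass(q)
  if (length(p) != length(q) ||
      (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))))
    stop("distributions must share one bin set", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must be probability vectors summing to 1", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Saturated chain-length distribution of a GC-MS profile
#'
#' Ground-truth counterpart of [chain_length_distribution()]: the profile's
#' saturated species concentrations binned over even carbons and
#' renormalized to sum to 1.
#'
#' @param profile A [gcms_profile()].
#' @param bins Even-carbon bins (default C8--C18).
#' @return A `chain_length_distribution`.
#' @export
gcms_chain_length_distribution <- function(profile, bins = seq(8L, 18L, 2L)) {
  stopifnot(inherits(profile, "gcms_profile"))
  sat <- profile[profile$unsaturation == 0, ]
  if (sum(sat$concentration) <= 0)
    stop("profile has no saturated mass", call. = FALSE)
  cl <- pmin(pmax(sat$chain_length, min(bins)), max(bins))
  p <- vapply(bins, function(b) sum(sat$concentration[cl == b]), 0)
  p <- p / sum(p)
  names(p) <- paste0("C", bins)
  structure(p, class = "chain_length_distribution", bins = as.integer(bins))
}

#' Unsaturation ratio of a GC-MS profile
#'
#' Summed unsaturated concentration over summed saturated concentration.
#'
#' @param profile A [gcms_profile()].
#' @return Non-negative scalar.
#' @export
gcms_unsaturation_ratio <- function(profile) {
  stopifnot(inherits(profile, "gcms_profile"))
  s <- sum(profile$concentration[profile$unsaturation == 0])
  if (s <= 0) stop("profile has no saturated mass", call. = FALSE)
  sum(profile$concentration[profile$unsaturation == 1]) / s
}
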