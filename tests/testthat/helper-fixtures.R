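# Shared fixtures: tiny axes/spectra and a chemical_maps constructor for
# composition/single-cell tests that do not need a real unmixing run.

toy_axis <- function(n = 40, lo = 2800, hi = 3050) seq(lo, hi, length.out = n)

# chemical_maps built directly from a truth array and a library
maps_from_truth <- function(lib, arr, residual = NULL,
                            config = unmix_config()) {
  structure(list(maps = arr, component = lib$component,
                 category = lib$category, chain_length = lib$chain_length,
                 ref_auc = library_auc(lib), wavenumber = lib$wavenumber,
                 residual = residual, config = config),
            class = "chemical_maps")
}

# fine-grid trapezoid oracle for window integrals of a sampled spectrum
# (piecewise-linear interpolation, independent of auc_window's weighting)
finegrid_auc <- function(s, window, n = 20001) {
  xs <- seq(window[1], window[2], length.out = n)
  ys <- stats::approx(s$wavenumber, s$intensity, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-n])) / 2
}

# brute-force grid search oracle for the 2-component pixel LASSO
grid_lasso_oracle <- function(d, S, beta, cmax = 2, res = 1e-3) {
  g <- seq(0, cmax, by = res)
  G <- S %*% t(S)
  b <- as.vector(S %*% d)
  dd <- sum(d^2)
  C1 <- matrix(g, length(g), length(g))
  C2 <- matrix(g, length(g), length(g), byrow = TRUE)
  obj <- 0.5 * dd - (b[1] * C1 + b[2] * C2) +
    0.5 * (G[1, 1] * C1^2 + 2 * G[1, 2] * C1 * C2 + G[2, 2] * C2^2) +
    beta * (C1 + C2)
  i <- arrayInd(which.min(obj), dim(obj))
  list(c = c(g[i[1]], g[i[2]]), objective = min(obj))
}

pixel_objective <- function(d, S, cvec, beta) {
  r <- d - as.vector(cvec %*% S)
  0.5 * sum(r^2) + beta * sum(abs(cvec))
}
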