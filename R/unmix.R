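# Pixel-wise L1-regularized (LASSO) spectral unmixing of hyperspectral stacks.
#
# Model: D = C S + E, with D the stack reshaped to (Npix x Nlambda), S the
# (K x Nlambda) reference matrix and C the per-pixel concentrations. Each
# pixel solves min_c 1/2 ||d - c S||^2 + beta ||c||_1 (optionally c >= 0);
# the L1 term suppresses crosstalk between spectrally overlapping components
# by favoring a few dominant components per pixel.

#' Construct a hyperspectral SRS stack
#'
#' @param wavenumber Strictly increasing axis (cm^-1), length N_lambda.
#' @param data Numeric array `Nx x Ny x N_lambda` of SRS intensities.
#' @return Object of class `srs_stack`.
#' @export
srs_stack <- function(wavenumber, data) {
  .validate_axis(wavenumber)
  if (length(dim(data)) != 3 || dim(data)[3] != length(wavenumber))
    stop("data must be an Nx x Ny x N_lambda array matching the axis",
         call. = FALSE)
  if (any(!is.finite(data)))
    stop("stack intensities must be finite", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber), data = data),
            class = "srs_stack")
}

#' @export
print.srs_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral SRS stack: %d x %d px, %d wavenumbers (%.0f-%.0f cm^-1)\n",
              d[1], d[2], d[3], min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Unmixing configuration
#'
#' @param beta L1 penalty weight (>= 0), on the normalized intensity scale.
#'   The default 1e-6 is the largest order of magnitude that recovers the
#'   ground-truth support on the bundled synthetic benchmark with a
#'   GC-MS-scaled library, where coefficients are inflated by inverse
#'   composition shares (see the methods vignette and [beta_sweep()]).
#' @param nonnegative Constrain concentrations to be non-negative
#'   (default `TRUE`; physical concentrations cannot be negative). Set
#'   `FALSE` for the unconstrained LASSO.
#' @param normalize Intensity normalization policy: `"median_norm"` scales
#'   the stack so the median per-pixel spectral L2 norm (over signal-bearing
#'   pixels, norm above 1e-3 of the maximum) is 1 before solving, so `beta`
#'   transfers across acquisitions; maps are rescaled back afterwards.
#'   `"none"` solves on raw intensities.
#' @param max_iterations Maximum coordinate-descent sweeps.
#' @param tolerance A pixel stops iterating when its objective decrease per
#'   sweep falls below `tolerance * (1 + |objective|)`.
#' @return Object of class `unmix_config`.
#' @export
unmix_config <- function(beta = 1e-6, nonnegative = TRUE,
                         normalize = c("median_norm", "none"),
                         max_iterations = 50000L, tolerance = 1e-8) {
  stopifnot(is.finite(beta), beta >= 0, tolerance > 0, max_iterations >= 1)
  structure(list(beta = beta, nonnegative = isTRUE(nonnegative),
                 normalize = match.arg(normalize),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "unmix_config")
}

# Cyclic coordinate descent on the Gram matrix, vectorized across pixels.
# D: Npix x Nlambda, S: K x Nlambda. Deterministic: zero start, fixed
# component order. Returns Npix x K coefficients.
.lasso_cd <- function(D, S, beta, nonnegative, max_iterations, tolerance) {
  K <- nrow(S)
  G <- S %*% t(S)
  gdiag <- diag(G)
  # all-zero rows (e.g. zero GC-MS share) stay inert at coefficient 0
  active <- which(gdiag > 0)
  if (length(active) == 0)
    stop("reference matrix has no non-zero row", call. = FALSE)
  B <- D %*% t(S)
  d2 <- rowSums(D^2)
  C <- matrix(0, nrow(D), K)
  # pixels are independent problems: each is frozen (and dropped from the
  # working set) once its own objective decrease falls below tolerance
  ip <- seq_len(nrow(D))
  Cw <- C; Bw <- B
  obj_prev <- 0.5 * d2
  for (it in seq_len(max_iterations)) {
    for (k in active) {
      z <- Bw[, k] - as.vector(Cw %*% G[, k]) + Cw[, k] * gdiag[k]
      Cw[, k] <- if (nonnegative) pmax(0, z - beta) / gdiag[k]
                 else sign(z) * pmax(0, abs(z) - beta) / gdiag[k]
    }
    CG <- Cw %*% G
    obj <- 0.5 * d2[ip] - rowSums(Cw * Bw) + 0.5 * rowSums(CG * Cw) +
      beta * rowSums(abs(Cw))
    done <- (obj_prev - obj) < tolerance * (1 + abs(obj))
    if (any(done)) {
      C[ip[done], ] <- Cw[done, , drop = FALSE]
      if (all(done)) { ip <- integer(0); break }
      keep <- !done
      ip <- ip[keep]
      Cw <- Cw[keep, , drop = FALSE]
      Bw <- Bw[keep, , drop = FALSE]
      obj <- obj[keep]
    }
    obj_prev <- obj
  }
  if (length(ip)) {
    C[ip, ] <- Cw
    warning(sprintf("%d pixel(s) did not reach tolerance in %d sweeps",
                    length(ip), max_iterations), call. = FALSE)
  }
  # exact KKT polish: solve the optimality system on each pixel's support,
  # adjusting the support until the KKT conditions hold; keeps the better
  # of the iterate and the polished solution so the objective never worsens
  pobj <- function(cv, b)
    -sum(cv * b) + 0.5 * sum(cv * as.vector(G %*% cv)) + beta * sum(abs(cv))
  for (i in seq_len(nrow(C))) {
    cp <- .kkt_polish(C[i, ], B[i, ], G, beta, nonnegative, active)
    if (!is.null(cp) && pobj(cp, B[i, ]) < pobj(C[i, ], B[i, ])) C[i, ] <- cp
  }
  C
}

# Active-set refinement of a pixel solution: solve G_AA c_A = b_A - beta*s_A
# on the current support, drop coordinates that cross zero, add the worst
# KKT violator, stop when optimal. Returns NULL when the support system is
# singular or the iteration does not settle.
.kkt_polish <- function(cvec, b, G, beta, nonnegative, active) {
  K <- length(cvec)
  # add-threshold just above the ~K * eps * ||G|| * ||c|| gradient noise
  # floor, so weakly determined components are still pulled into the support
  tol <- 1e-14 * (1 + max(abs(b)))
  A <- which(if (nonnegative) cvec > 0 else cvec != 0)
  s <- sign(cvec)
  for (it in seq_len(4L * K + 4L)) {
    if (length(A) == 0) {
      grad_ok <- if (nonnegative) all(b[active] <= beta + tol)
                 else all(abs(b[active]) <= beta + tol)
      if (grad_ok) return(numeric(K))
      j <- if (nonnegative) active[which.max(b[active])]
           else active[which.max(abs(b[active]))]
      A <- j
      s[j] <- if (nonnegative) 1 else sign(b[j])
      next
    }
    sol <- tryCatch(solve(G[A, A, drop = FALSE],
                          b[A] - beta * (if (nonnegative) 1 else s[A])),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    bad <- if (nonnegative) sol <= 0 else sign(sol) * s[A] <= 0
    if (any(bad)) {
      A <- A[!bad]
      next
    }
    cand <- numeric(K)
    cand[A] <- sol
    g <- b - as.vector(G[, A, drop = FALSE] %*% sol)
    viol <- if (nonnegative) g - beta else abs(g) - beta
    viol[A] <- -Inf
    viol[-active] <- -Inf
    if (max(viol) <= tol) return(cand)
    j <- which.max(viol)
    A <- c(A, j)
    s[j] <- if (nonnegative) 1 else sign(g[j])
  }
  NULL
}

#' Unmix a single pixel spectrum
#'
#' Solves the per-pixel LASSO `min_c 1/2 ||d - c S||^2 + beta ||c||_1`
#' (with `c >= 0` when configured) by cyclic coordinate descent.
#'
#' @param d Numeric spectrum vector, length N_lambda.
#' @param S Reference matrix, K x N_lambda (rows not all-zero).
#' @param config An [unmix_config()]. Intensity normalization is a
#'   stack-level policy and is not applied here.
#' @return Numeric concentration vector of length K.
#' @export
unmix_pixel <- function(d, S, config = unmix_config()) {
  stopifnot(inherits(config, "unmix_config"))
  S <- rbind(S)
  if (length(d) != ncol(S))
    stop("spectrum length must match reference matrix columns", call. = FALSE)
  c(.lasso_cd(matrix(d, nrow = 1), S, config$beta, config$nonnegative,
              config$max_iterations, config$tolerance))
}

#' Unmix a hyperspectral stack into chemical concentration maps
#'
#' Applies the per-pixel LASSO to every pixel of the stack against the
#' library references. When the library axis differs from the stack axis the
#' references are resampled onto the stack axis by linear interpolation
#' (extrapolation is refused). Deterministic given inputs and configuration.
#'
#' @param stack An [srs_stack()].
#' @param lib A [reference_library()] (plain normalized or GC-MS scaled).
#' @param config An [unmix_config()].
#' @param residual Keep the residual stack `E = D - C S`? Default `TRUE`.
#' @return Object of class `chemical_maps`: per-component concentration
#'   images (`maps`, Nx x Ny x K), component metadata, reference AUCs, and
#'   optionally the residual array.
#' @export
unmix_stack <- function(stack, lib, config = unmix_config(), residual = TRUE) {
  stopifnot(inherits(stack, "srs_stack"), inherits(lib, "srs_library"))
  lib <- resample_library(lib, stack$wavenumber)
  dims <- dim(stack$data)
  npix <- dims[1] * dims[2]
  D <- matrix(stack$data, npix, dims[3])
  scale <- 1
  if (config$normalize == "median_norm") {
    norms <- sqrt(rowSums(D^2))
    # median over signal-bearing pixels; numerically empty background
    # pixels (norm below 1e-3 of the max) would otherwise set the scale
    signal <- norms > 1e-3 * max(norms)
    m <- stats::median(norms[signal])
    if (is.finite(m) && m > 0) scale <- m
    D <- D / scale
  }
  C <- .lasso_cd(D, lib$intensity, config$beta, config$nonnegative,
                 config$max_iterations, config$tolerance) * scale
  maps <- array(C, dim = c(dims[1], dims[2], nrow(lib$intensity)))
  E <- if (residual) array(stack$data - array(C %*% lib$intensity, dims), dims)
       else NULL
  structure(list(maps = maps, component = lib$component,
                 category = lib$category, chain_length = lib$chain_length,
                 ref_auc = library_auc(lib), wavenumber = lib$wavenumber,
                 residual = E, config = config),
            class = "chemical_maps")
}

#' @export
print.chemical_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("Chemical maps: %d x %d px, %d components (%s)\n",
              d[1], d[2], d[3], paste(x$component, collapse = ", ")))
  invisible(x)
}

#' Resample a reference library onto a target axis
#'
#' Linear interpolation; refuses to extrapolate beyond the library axis.
#'
#' @param lib A [reference_library()].
#' @param wavenumber Target axis.
#' @return A library on the target axis (unchanged if axes already match).
#' @export
resample_library <- function(lib, wavenumber) {
  stopifnot(inherits(lib, "srs_library"))
  if (isTRUE(all.equal(lib$wavenumber, as.numeric(wavenumber)))) return(lib)
  if (min(wavenumber) < min(lib$wavenumber) ||
      max(wavenumber) > max(lib$wavenumber))
    stop("stack axis extends beyond library axis; cannot extrapolate",
         call. = FALSE)
  intensity <- t(apply(lib$intensity, 1, function(y)
    stats::approx(lib$wavenumber, y, xout = wavenumber)$y))
  out <- reference_library(wavenumber, intensity, lib$component)
  attr(out, "gcms_share") <- attr(lib, "gcms_share")
  out
}

.map_matrix <- function(maps) {
  d <- dim(maps$maps)
  matrix(maps$maps, d[1] * d[2], d[3])
}

#' Reconstruct a component-restricted hyperspectral stack
#'
#' `stack(x, y, lambda) = sum_k C_k(x, y) S_k(lambda)` over the selected
#' components; used e.g. to form the saturated-only stack feeding the
#' per-pixel CH2/CH3 chain-length estimate.
#'
#' @param maps A [unmix_stack()] result.
#' @param lib The [reference_library()] the maps were fitted with.
#' @param subset Character vector of component names.
#' @return An [srs_stack()].
#' @export
reconstruct_component_stack <- function(maps, lib, subset) {
  stopifnot(inherits(maps, "chemical_maps"), inherits(lib, "srs_library"))
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  unknown <- setdiff(subset, intersect(maps$component, lib$component))
  if (length(unknown))
    stop("unknown component name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lib <- resample_library(lib, maps$wavenumber)
  idx <- match(subset, maps$component)
  C <- .map_matrix(maps)[, idx, drop = FALSE]
  S <- lib$intensity[subset, , drop = FALSE]
  d <- dim(maps$maps)
  srs_stack(lib$wavenumber, array(C %*% S, c(d[1], d[2], ncol(S))))
}

#' Combined fatty-acid map
#'
#' Pixel-wise sum of all saturated and unsaturated component maps (protein
#' excluded), visualizing total fatty-acid concentration. With
#' `weights = "auc"` each map is weighted by its reference's trapezoidal
#' area first, which converts GC-MS-scaled coefficients back to comparable
#' mass units.
#'
#' @param maps A [unmix_stack()] result with >= 1 fatty-acid component.
#' @param weights `"none"` (plain sum, default) or `"auc"`.
#' @return Numeric Nx x Ny matrix.
#' @export
combined_fatty_acid_map <- function(maps, weights = c("none", "auc")) {
  stopifnot(inherits(maps, "chemical_maps"))
  weights <- match.arg(weights)
  fa <- which(maps$category != "protein")
  if (length(fa) == 0) stop("no fatty-acid components in maps", call. = FALSE)
  d <- dim(maps$maps)
  w <- if (weights == "auc") maps$ref_auc[fa] else rep(1, length(fa))
  matrix(.map_matrix(maps)[, fa, drop = FALSE] %*% w, d[1], d[2])
}

#' Residual/sparsity curves over a grid of L1 penalties
#'
#' Utility for choosing `beta`: runs the unmixing at each penalty and
#' reports the relative residual norm and the fraction of exactly-zero
#' coefficients.
#'
#' @param stack An [srs_stack()].
#' @param lib A [reference_library()].
#' @param betas Numeric vector of penalties.
#' @param config Base [unmix_config()]; its `beta` is overridden.
#' @return Data frame with columns `beta`, `relative_residual`, `sparsity`.
#' @export
beta_sweep <- function(stack, lib, betas, config = unmix_config()) {
  stopifnot(length(betas) >= 1, all(betas >= 0))
  dn <- sqrt(sum(stack$data^2))
  out <- lapply(betas, function(b) {
    config$beta <- b
    m <- unmix_stack(stack, lib, config, residual = TRUE)
    data.frame(beta = b,
               relative_residual = sqrt(sum(m$residual^2)) / dn,
               sparsity = mean(.map_matrix(m) == 0))
  })
  do.call(rbind, out)
}
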