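# Reference libraries of pure-component spectra and GC-MS composition profiles.

#' Parse fatty-acid species labels of the form "Cn:u"
#'
#' @param species Character vector like `"C14:0"`, `"C16:1"`.
#' @return Data frame with columns `species`, `chain_length`, `unsaturation`.
#' @export
parse_species <- function(species) {
  m <- regmatches(species, regexec("^C([0-9]+):([0-9]+)$", species))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("malformed species label(s): ", paste(species[bad], collapse = ", "),
         " (expected 'Cn:u')", call. = FALSE)
  n <- vapply(m, function(g) as.integer(g[2]), 0L)
  u <- vapply(m, function(g) as.integer(g[3]), 0L)
  bad <- n %% 2L != 0L | n < 6L | n > 20L | !(u %in% c(0L, 1L))
  if (any(bad))
    stop("invalid species (need even chain length 6-20, unsaturation 0 or 1): ",
         paste(species[bad], collapse = ", "), call. = FALSE)
  data.frame(species = species, chain_length = n, unsaturation = u,
             stringsAsFactors = FALSE)
}

#' Construct a GC-MS fatty-acid composition profile
#'
#' Bulk-culture fatty-acid quantification, one concentration per species.
#' Used both to weight (augment) reference spectra before unmixing and as
#' ground truth when validating recovered chain-length distributions.
#'
#' @param species Character vector of `Cn:u` labels (even n in 6--20, u 0/1).
#' @param concentration Non-negative concentrations (mg/L or relative units).
#' @return A data frame of class `gcms_profile` with columns `species`,
#'   `chain_length`, `unsaturation`, `concentration`.
#' @export
gcms_profile <- function(species, concentration) {
  df <- parse_species(species)
  if (anyDuplicated(df$species))
    stop("duplicate species in profile", call. = FALSE)
  if (length(concentration) != nrow(df) || any(!is.finite(concentration)) ||
      any(concentration < 0))
    stop("concentrations must be finite, non-negative, one per species",
         call. = FALSE)
  if (all(concentration == 0))
    stop("profile needs at least one positive concentration", call. = FALSE)
  df$concentration <- as.numeric(concentration)
  class(df) <- c("gcms_profile", "data.frame")
  df
}

#' Construct a reference library of pure-component spectra
#'
#' Holds the matrix S of pixel-wise unmixing: one spectrum per component,
#' all on one shared wavenumber axis. Components are a protein reference
#' (at most one), saturated fatty acids `Cn:0` carrying their chain length,
#' and at most one composite unsaturated reference (named `unsat`).
#'
#' @param wavenumber Shared strictly increasing axis (cm^-1).
#' @param intensity Numeric matrix, one row per component (K x N_lambda).
#' @param component Unique component names; `"protein"`, `"Cn:0"` labels, or
#'   `"unsat"`. Categories are inferred from the names.
#' @return An object of class `srs_library`.
#' @export
reference_library <- function(wavenumber, intensity, component) {
  .validate_axis(wavenumber)
  intensity <- rbind(intensity)
  if (ncol(intensity) != length(wavenumber))
    stop("intensity must have one column per axis point", call. = FALSE)
  if (nrow(intensity) != length(component) || anyDuplicated(component))
    stop("component names must be unique, one per spectrum row", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("reference intensities must be finite", call. = FALSE)
  category <- ifelse(component == "protein", "protein",
              ifelse(component == "unsat", "unsaturated", "saturated"))
  chain_length <- rep(NA_integer_, length(component))
  sat <- category == "saturated"
  if (any(sat)) {
    ps <- parse_species(component[sat])
    if (any(ps$unsaturation != 0))
      stop("saturated component labels must be Cn:0", call. = FALSE)
    chain_length[sat] <- ps$chain_length
  }
  if (sum(category == "protein") > 1 || sum(category == "unsaturated") > 1)
    stop("at most one protein and one unsaturated composite entry", call. = FALSE)
  rownames(intensity) <- component
  structure(list(wavenumber = as.numeric(wavenumber), intensity = intensity,
                 component = component, category = category,
                 chain_length = chain_length),
            class = "srs_library")
}

#' @export
print.srs_library <- function(x, ...) {
  cat(sprintf("SRS reference library: %d components on %d wavenumbers (%.0f-%.0f cm^-1)\n",
              length(x$component), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  cat("  ", paste(x$component, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one component of a library as a spectrum
#' @param lib An [reference_library()].
#' @param component Component name.
#' @return An [srs_spectrum()].
#' @export
library_spectrum <- function(lib, component) {
  stopifnot(inherits(lib, "srs_library"))
  if (!component %in% lib$component)
    stop("unknown component: ", component, call. = FALSE)
  srs_spectrum(lib$wavenumber, lib$intensity[component, ])
}

#' Normalize every reference in a library to unit area
#' @param lib An [reference_library()].
#' @return The library with each row at unit trapezoidal area.
#' @export
normalize_library <- function(lib) {
  stopifnot(inherits(lib, "srs_library"))
  for (k in seq_along(lib$component)) {
    a <- trapz(lib$wavenumber, lib$intensity[k, ])
    if (a <= 0) stop("component ", lib$component[k], " has non-positive area",
                     call. = FALSE)
    lib$intensity[k, ] <- lib$intensity[k, ] / a
  }
  lib
}

#' Per-component trapezoidal areas of a library
#' @param lib An [reference_library()].
#' @return Named numeric vector of areas.
#' @export
library_auc <- function(lib) {
  stopifnot(inherits(lib, "srs_library"))
  a <- apply(lib$intensity, 1, function(y) trapz(lib$wavenumber, y))
  names(a) <- lib$component
  a
}

#' Composite unsaturated reference from GC-MS weights
#'
#' Unsaturated fatty acids share a dominant broad band and a distinct
#' ~3000 cm^-1 marker but cannot be speciated by chain length, so a single
#' composite reference is formed: the convex combination of the normalized
#' input spectra with weights proportional to the GC-MS concentrations of the
#' corresponding unsaturated species.
#'
#' @param specs List of [srs_spectrum()] on one shared axis.
#' @param weights Non-negative weights, one per spectrum, not all zero.
#' @return A unit-area composite `srs_spectrum`.
#' @export
composite_unsaturated_reference <- function(specs, weights) {
  stopifnot(length(specs) >= 1, length(weights) == length(specs))
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  ax <- specs[[1]]$wavenumber
  for (s in specs)
    if (!isTRUE(all.equal(s$wavenumber, ax)))
      stop("all spectra must share one wavenumber axis", call. = FALSE)
  w <- weights / sum(weights)
  y <- rep(0, length(ax))
  for (i in seq_along(specs))
    y <- y + w[i] * normalize_spectrum(specs[[i]])$intensity
  srs_spectrum(ax, y)
}

#' Rescale a reference library by GC-MS composition shares
#'
#' Augments pixel-wise LASSO unmixing with bulk-culture prior knowledge: each
#' saturated reference is multiplied by its species' share of the total
#' fatty-acid concentration, and the composite unsaturated reference by the
#' summed share of all unsaturated species. Shares are computed over
#' fatty-acid species only and sum to 1; the protein reference passes through
#' untouched. Species present in the profile but missing from the library are
#' dropped with a warning and their mass reassigned proportionally.
#'
#' @param lib A [reference_library()] (references should be unit-area
#'   normalized; see [normalize_library()]).
#' @param profile A [gcms_profile()] containing every saturated library
#'   species (possibly at zero concentration).
#' @return A `srs_library` with scaled fatty-acid rows and a
#'   `gcms_share` attribute (named shares used).
#' @export
scale_references_by_gcms <- function(lib, profile) {
  stopifnot(inherits(lib, "srs_library"), inherits(profile, "gcms_profile"))
  sat_idx <- which(lib$category == "saturated")
  uns_idx <- which(lib$category == "unsaturated")
  if (length(sat_idx) + length(uns_idx) == 0)
    stop("library has no fatty-acid components", call. = FALSE)

  sat_lib <- lib$component[sat_idx]
  prof_sat <- profile[profile$unsaturation == 0, ]
  prof_uns <- profile[profile$unsaturation == 1, ]
  missing_in_profile <- setdiff(sat_lib, prof_sat$species)
  if (length(missing_in_profile))
    stop("saturated library species absent from profile: ",
         paste(missing_in_profile, collapse = ", "), call. = FALSE)

  keep_sat <- prof_sat$species %in% sat_lib
  if (any(!keep_sat)) {
    warning("profile species absent from library dropped (mass reassigned): ",
            paste(prof_sat$species[!keep_sat], collapse = ", "), call. = FALSE)
    prof_sat <- prof_sat[keep_sat, ]
  }
  uns_total <- sum(prof_uns$concentration)
  if (length(uns_idx) == 0 && uns_total > 0) {
    warning("unsaturated species in profile but no composite in library; ",
            "mass reassigned proportionally", call. = FALSE)
    uns_total <- 0
  }
  total <- sum(prof_sat$concentration) + uns_total
  if (total <= 0)
    stop("all fatty-acid shares are zero; augmentation degenerate", call. = FALSE)

  shares <- numeric(length(lib$component))
  names(shares) <- lib$component
  shares[prof_sat$species] <- prof_sat$concentration / total
  if (length(uns_idx)) shares[uns_idx] <- uns_total / total
  out <- lib
  fa <- c(sat_idx, uns_idx)
  out$intensity[fa, ] <- out$intensity[fa, , drop = FALSE] * shares[fa]
  attr(out, "gcms_share") <- shares[fa]
  out
}
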