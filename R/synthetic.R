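# Synthetic data: model reference spectra, GC-MS profiles, hyperspectral
# scenes with ground truth, and cell-length growth trajectories. All
# generators are pure functions of their parameters and seed.

# Run code with a temporary RNG seed, restoring caller RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

.gauss <- function(x, center, width, amplitude) {
  amplitude * exp(-0.5 * ((x - center) / width)^2)
}

#' Load the Gaussian-band spectral model parameters
#'
#' Band centers, widths and amplitudes of the synthetic C-H-region spectral
#' model live in one YAML configuration file bundled with the package, not
#' in code.
#'
#' @param path Optional path to an alternative YAML file.
#' @return Nested list of model parameters.
#' @export
spectral_model_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spectral_model.yaml", package = "srsfa")
  yaml::read_yaml(path)
}

.model_axis <- function(params) {
  seq(params$axis$min_cm1, params$axis$max_cm1,
      length.out = params$axis$n_points)
}

.band_field <- function(b, field) if (is.null(b[[field]])) 0 else b[[field]]

.saturated_model_spectrum <- function(axis, n, params) {
  p <- params$saturated
  y <- rep(0, length(axis))
  for (b in p$ch2_bands)
    y <- y + .gauss(axis, b$center + .band_field(b, "center_slope") * (n - 6),
                    b$width + .band_field(b, "width_slope") * (n - 6),
                    b$amplitude * (n - 2))
  for (b in p$ch3_bands)
    y <- y + .gauss(axis, b$center + .band_field(b, "center_slope") * (n - 6),
                    b$width + .band_field(b, "width_slope") * (n - 6),
                    b$amplitude)
  y
}

.unsaturated_model_spectrum <- function(axis, n, params) {
  y <- rep(0, length(axis))
  for (b in params$unsaturated$bands)
    y <- y + .gauss(axis, b$center, b$width,
                    b$amplitude + b$amplitude_slope * (n - 12))
  y
}

#' Generate a model reference library
#'
#' Builds noiseless C-H-region reference spectra from the Gaussian-band
#' model: a broad protein band, saturated fatty acids whose CH2-band
#' amplitude grows as (n - 2) with fixed CH3 bands (so the CH2/CH3 AUC
#' ratio increases strictly with chain length), and a composite unsaturated
#' reference carrying the ~3000 cm^-1 marker, formed as a weighted average
#' of the model's individual unsaturated species.
#'
#' @param species Components to include: `"protein"`, `"Cn:0"` labels
#'   (even n, 6--20) and/or `"unsat"`.
#' @param params Model parameters ([spectral_model_params()]).
#' @param unsat_weights Optional [gcms_profile()] (its unsaturated species'
#'   concentrations weight the composite) or a numeric vector over the
#'   model's unsaturated species; default equal weights.
#' @param normalize Return unit-area references? Default `TRUE`.
#' @return A [reference_library()].
#' @export
make_reference_spectra <- function(species = c("protein", "C8:0", "C10:0",
                                               "C12:0", "C14:0", "C16:0",
                                               "C18:0", "unsat"),
                                   params = spectral_model_params(),
                                   unsat_weights = NULL, normalize = TRUE) {
  axis <- .model_axis(params)
  rows <- matrix(0, length(species), length(axis))
  for (i in seq_along(species)) {
    sp <- species[i]
    if (sp == "protein") {
      y <- rep(0, length(axis))
      for (b in params$protein$bands)
        y <- y + .gauss(axis, b$center, b$width, b$amplitude)
    } else if (sp == "unsat") {
      us <- parse_species(unlist(params$unsaturated$species))
      w <- rep(1, nrow(us))
      if (inherits(unsat_weights, "gcms_profile")) {
        w <- vapply(us$species, function(s) {
          j <- match(s, unsat_weights$species)
          if (is.na(j)) 0 else unsat_weights$concentration[j]
        }, 0)
        if (sum(w) <= 0) w <- rep(1, nrow(us))
      } else if (is.numeric(unsat_weights)) {
        stopifnot(length(unsat_weights) == nrow(us))
        w <- unsat_weights
      }
      specs <- lapply(us$chain_length, function(n)
        srs_spectrum(axis, .unsaturated_model_spectrum(axis, n, params)))
      y <- composite_unsaturated_reference(specs, w)$intensity
    } else {
      ps <- parse_species(sp)
      if (ps$unsaturation != 0)
        stop("individual unsaturated species are not library components; ",
             "use 'unsat'", call. = FALSE)
      y <- .saturated_model_spectrum(axis, ps$chain_length, params)
    }
    rows[i, ] <- y
  }
  lib <- reference_library(axis, rows, species)
  if (normalize) normalize_library(lib) else lib
}

#' Add Gaussian measurement noise to a spectrum
#'
#' Additive white noise with standard deviation `max(intensity) / snr`
#' (SNR defined as peak signal over noise sigma).
#'
#' @param s An [srs_spectrum()].
#' @param snr Signal-to-noise ratio (> 0).
#' @param seed Optional RNG seed.
#' @return A noisy `srs_spectrum` (values may dip slightly below zero).
#' @export
add_spectrum_noise <- function(s, snr, seed = NULL) {
  stopifnot(inherits(s, "srs_spectrum"), snr > 0)
  .with_seed(seed, {
    sigma <- max(s$intensity) / snr
    srs_spectrum(s$wavenumber, s$intensity + stats::rnorm(length(s$intensity),
                                                          sd = sigma))
  })
}

#' Simulate noisy replicate spectra of saturated standards
#'
#' Pure saturated fatty-acid standards measured with additive Gaussian
#' noise; replicates are independent noise draws. Feeds
#' [fit_chain_length_calibration()].
#'
#' @param chain_lengths Even carbon numbers (default C6--C20).
#' @param snr Signal-to-noise ratio (peak / sigma). Default 20.
#' @param n_replicates Noise replicates per standard. Default 6.
#' @param seed RNG seed.
#' @param params Model parameters.
#' @return List with `spectra` (list of [srs_spectrum()]) and
#'   `chain_length` (integer vector aligned to it).
#' @export
simulate_standard_replicates <- function(chain_lengths = seq(6L, 20L, 2L),
                                         snr = 20, n_replicates = 6L,
                                         seed = 1L,
                                         params = spectral_model_params()) {
  stopifnot(all(chain_lengths %% 2 == 0), all(chain_lengths >= 6),
            all(chain_lengths <= 20))
  axis <- .model_axis(params)
  .with_seed(seed, {
    spectra <- list()
    cl <- integer(0)
    for (n in chain_lengths) {
      clean <- srs_spectrum(axis, .saturated_model_spectrum(axis, n, params))
      for (r in seq_len(n_replicates)) {
        spectra[[length(spectra) + 1L]] <- add_spectrum_noise(clean, snr)
        cl <- c(cl, as.integer(n))
      }
    }
    list(spectra = spectra, chain_length = cl)
  })
}

#' Preset GC-MS composition profiles
#'
#' Fixture profiles emulating the qualitative shapes of thioesterase
#' production strains: a short-chain producer dominated by octanoic acid
#' (C8:0), a mixed medium/long-chain producer with myristic acid (C14:0)
#' as the largest component, and a long-chain producer with large C14:0 and
#' C16:0 contributions. The numeric fractions are synthetic fixtures, not
#' measured values.
#'
#' @param preset One of `"short_chain_producer"`, `"mixed_producer"`,
#'   `"long_chain_producer"`, or `"custom"` (then supply `species` and
#'   `concentration`).
#' @param species,concentration For `preset = "custom"`.
#' @return A [gcms_profile()] with fractions summing to 1.
#' @export
make_gcms_profile <- function(preset = c("short_chain_producer",
                                         "mixed_producer",
                                         "long_chain_producer", "custom"),
                              species = NULL, concentration = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    p <- gcms_profile(species, concentration)
  } else {
    tbl <- switch(preset,
      short_chain_producer = c("C8:0" = 0.72, "C10:0" = 0.09, "C12:0" = 0.05,
                               "C14:0" = 0.06, "C16:0" = 0.04, "C18:0" = 0,
                               "C12:1" = 0, "C14:1" = 0,
                               "C16:1" = 0.025, "C18:1" = 0.015),
      mixed_producer = c("C8:0" = 0.08, "C10:0" = 0.10, "C12:0" = 0.16,
                         "C14:0" = 0.30, "C16:0" = 0.14, "C18:0" = 0.06,
                         "C12:1" = 0.03, "C14:1" = 0.05, "C16:1" = 0.05,
                         "C18:1" = 0.03),
      long_chain_producer = c("C8:0" = 0.01, "C10:0" = 0.03, "C12:0" = 0.06,
                              "C14:0" = 0.32, "C16:0" = 0.30, "C18:0" = 0.12,
                              "C12:1" = 0, "C14:1" = 0.04, "C16:1" = 0.07,
                              "C18:1" = 0.05))
    p <- gcms_profile(names(tbl), unname(tbl))
  }
  p$concentration <- p$concentration / sum(p$concentration)
  p
}

#' Scene specification for the synthetic generator
#'
#' Geometry, composition and noise of a synthetic field of view: rod-shaped
#' cells (protein, with a fraction of high producers accumulating fatty
#' acid) and extracellular fatty-acid droplets on a dark background.
#' Lengths are in micrometers; the default pixel size is 150 nm.
#'
#' @param nx,ny Image size in pixels.
#' @param pixel_size_um Pixel size (um).
#' @param n_cells Number of rod-shaped cells (placed without overlap).
#' @param cell_length_um,cell_width_um Length/width ranges of the rods.
#' @param n_droplets Number of circular extracellular droplets (may touch
#'   cells).
#' @param droplet_radius_um Droplet radius range.
#' @param protein_level In-cell protein concentration (arbitrary units).
#' @param high_producer_fraction Fraction of cells that are high producers.
#' @param high_fa_level,low_fa_level In-cell fatty-acid concentration of
#'   high/low producers.
#' @param droplet_fa_level Fatty-acid concentration inside droplets.
#' @param snr Scene signal-to-noise ratio: mean foreground peak signal over
#'   the additive Gaussian noise sigma.
#' @param seed RNG seed.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(nx = 256L, ny = 256L, pixel_size_um = 0.15,
                       n_cells = 20L, cell_length_um = c(1, 2),
                       cell_width_um = c(0.6, 0.9),
                       n_droplets = 10L, droplet_radius_um = c(0.45, 1.2),
                       protein_level = 1.0, high_producer_fraction = 0.1,
                       high_fa_level = 1.5, low_fa_level = 0.05,
                       droplet_fa_level = 2.0, snr = 20, seed = 1L) {
  stopifnot(nx >= 8, ny >= 8, snr > 0, n_cells >= 0, n_droplets >= 0,
            high_producer_fraction >= 0, high_producer_fraction <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

# Pixel set of a rod (segment dilated by width/2), 1-based indices.
.rod_pixels <- function(nx, ny, cx, cy, len_px, wid_px, theta) {
  half <- len_px / 2 - wid_px / 2  # half-length of the center segment
  half <- max(half, 0)
  r <- wid_px / 2
  ex <- half * cos(theta); ey <- half * sin(theta)
  x0 <- cx - ex; y0 <- cy - ey; x1 <- cx + ex; y1 <- cy + ey
  xr <- max(1, floor(min(x0, x1) - r - 1)):min(nx, ceiling(max(x0, x1) + r + 1))
  yr <- max(1, floor(min(y0, y1) - r - 1)):min(ny, ceiling(max(y0, y1) + r + 1))
  g <- expand.grid(x = xr, y = yr)
  vx <- x1 - x0; vy <- y1 - y0
  vv <- vx^2 + vy^2
  t <- if (vv > 0) pmin(1, pmax(0, ((g$x - x0) * vx + (g$y - y0) * vy) / vv))
       else rep(0, nrow(g))
  d2 <- (g$x - (x0 + t * vx))^2 + (g$y - (y0 + t * vy))^2
  g[d2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic hyperspectral scene with ground truth
#'
#' Places rod-shaped cells by rejection sampling (no overlap between cells;
#' a packing error is raised after 1000 failed attempts per cell) and
#' circular droplets (which may touch cells), assigns per-compartment
#' compositions from a GC-MS profile restricted to the library's fatty-acid
#' components, and synthesizes `stack = truth x references + noise` at the
#' requested SNR. Deterministic given the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @param lib A unit-area-normalized [reference_library()] (e.g. from
#'   [make_reference_spectra()]).
#' @param profile A [gcms_profile()] giving the fatty-acid mixture of
#'   producers and droplets.
#' @return List with `stack` ([srs_stack()]), and `truth`: per-component
#'   concentration array, `cell_mask`, `droplet_mask`, per-cell `regions`
#'   table, fatty-acid `shares`, noise `sigma`.
#' @export
make_scene <- function(spec, lib, profile) {
  stopifnot(inherits(spec, "scene_spec"), inherits(lib, "srs_library"),
            inherits(profile, "gcms_profile"))
  nx <- spec$nx; ny <- spec$ny
  px <- spec$pixel_size_um
  K <- length(lib$component)

  # fatty-acid shares over the library's fatty-acid components
  scaled <- suppressWarnings(scale_references_by_gcms(normalize_library(lib),
                                                      profile))
  shares <- attr(scaled, "gcms_share")

  .with_seed(spec$seed, {
    truth <- array(0, c(nx, ny, K))
    occupied <- matrix(FALSE, nx, ny)
    cell_mask <- matrix(0L, nx, ny)
    droplet_mask <- matrix(0L, nx, ny)
    n_high <- round(spec$high_producer_fraction * spec$n_cells)
    is_high <- rep(FALSE, spec$n_cells)
    if (n_high > 0) is_high[sample.int(spec$n_cells, n_high)] <- TRUE

    for (i in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        len_px <- stats::runif(1, spec$cell_length_um[1], spec$cell_length_um[2]) / px
        wid_px <- stats::runif(1, spec$cell_width_um[1], spec$cell_width_um[2]) / px
        margin <- len_px / 2 + 1
        if (nx - margin <= 1 + margin || ny - margin <= 1 + margin)
          stop("image too small for the requested cell size; packing error",
               call. = FALSE)
        cx <- stats::runif(1, 1 + margin, nx - margin)
        cy <- stats::runif(1, 1 + margin, ny - margin)
        theta <- stats::runif(1, 0, pi)
        pxs <- .rod_pixels(nx, ny, cx, cy, len_px, wid_px, theta)
        if (nrow(pxs) == 0) next
        idx <- cbind(pxs$x, pxs$y)
        if (any(occupied[idx])) next
        occupied[idx] <- TRUE
        cell_mask[idx] <- i
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place cell ", i, " in 1000 attempts; packing error",
             call. = FALSE)
    }

    for (j in seq_len(spec$n_droplets)) {
      r_px <- stats::runif(1, spec$droplet_radius_um[1],
                           spec$droplet_radius_um[2]) / px
      cx <- stats::runif(1, 1 + r_px, nx - r_px)
      cy <- stats::runif(1, 1 + r_px, ny - r_px)
      xr <- max(1, floor(cx - r_px)):min(nx, ceiling(cx + r_px))
      yr <- max(1, floor(cy - r_px)):min(ny, ceiling(cy + r_px))
      g <- expand.grid(x = xr, y = yr)
      g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r_px^2, , drop = FALSE]
      droplet_mask[cbind(g$x, g$y)] <- j
    }

    prot_k <- which(lib$category == "protein")
    fa_names <- names(shares)
    fa_k <- match(fa_names, lib$component)
    tm <- matrix(truth, nx * ny, K)
    cellv <- as.vector(cell_mask)
    dropv <- as.vector(droplet_mask)
    if (length(prot_k))
      tm[cellv > 0, prot_k] <- spec$protein_level
    fa_level <- ifelse(is_high, spec$high_fa_level, spec$low_fa_level)
    for (i in seq_len(spec$n_cells)) {
      sel <- cellv == i
      tm[sel, fa_k] <- tm[sel, fa_k, drop = FALSE] +
        rep(fa_level[i] * shares, each = sum(sel))
    }
    sel <- dropv > 0
    tm[sel, fa_k] <- tm[sel, fa_k, drop = FALSE] +
      rep(spec$droplet_fa_level * shares, each = sum(sel))

    clean <- tm %*% lib$intensity
    fg <- cellv > 0 | dropv > 0
    sigma <- if (any(fg)) mean(apply(clean[fg, , drop = FALSE], 1, max)) / spec$snr
             else 0
    noisy <- clean + matrix(stats::rnorm(length(clean), sd = sigma),
                            nrow(clean), ncol(clean))

    regions <- data.frame(region = seq_len(spec$n_cells),
                          high_producer = is_high,
                          area = as.integer(vapply(seq_len(spec$n_cells),
                                                   function(i) sum(cellv == i), 0L)),
                          protein_level = spec$protein_level,
                          fa_level = fa_level)
    list(stack = srs_stack(lib$wavenumber,
                           array(noisy, c(nx, ny, length(lib$wavenumber)))),
         truth = array(tm, c(nx, ny, K)), components = lib$component,
         cell_mask = cell_mask, droplet_mask = droplet_mask,
         regions = regions, shares = shares, sigma = sigma)
  })
}

#' Generate synthetic cell-length growth trajectories
#'
#' Exponential elongation `L(t) = L0 exp(mu t)` with multiplicative
#' log-normal measurement noise; the cell divides (length halves) once the
#' true length exceeds the division threshold. Deterministic per seed.
#'
#' @param n_cells Number of cells.
#' @param mu_true True elongation rate (1/min). The default 0.0115
#'   corresponds to a ~60 min doubling time, typical of slow growth at
#'   31 C on minimal-medium pads; at 20 min frames a division then drops
#'   the observed length by ~37%, comfortably past the 30% detection
#'   threshold.
#' @param dt_min Frame spacing (minutes). Default 20.
#' @param noise_sd Multiplicative length noise SD (e.g. 0.02 = 2%).
#' @param division_length_um Length triggering division.
#' @param frames Frames per trajectory (>= 3).
#' @param length0_um Initial length range (um).
#' @param seed RNG seed.
#' @return Data frame `cell_id`, `frame`, `time_min`, `length_um` with the
#'   noiseless lengths in column `length_true_um`.
#' @export
make_growth_trajectories <- function(n_cells = 50L, mu_true = 0.0115,
                                     dt_min = 20, noise_sd = 0.02,
                                     division_length_um = 4,
                                     frames = 30L, length0_um = c(1.5, 2.5),
                                     seed = 1L) {
  stopifnot(mu_true >= 0, frames >= 3, n_cells >= 1)
  .with_seed(seed, {
    rows <- lapply(seq_len(n_cells), function(i) {
      L <- stats::runif(1, length0_um[1], length0_um[2])
      Lt <- numeric(frames)
      for (k in seq_len(frames)) {
        Lt[k] <- L
        L <- L * exp(mu_true * dt_min)
        if (L > division_length_um) L <- L / 2
      }
      eps <- if (noise_sd > 0) exp(stats::rnorm(frames, sd = noise_sd))
             else rep(1, frames)
      data.frame(cell_id = i, frame = seq_len(frames),
                 time_min = (seq_len(frames) - 1) * dt_min,
                 length_um = Lt * eps, length_true_um = Lt)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
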