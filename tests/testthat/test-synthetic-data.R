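# Generators: spectral model, GC-MS presets, scenes with ground truth,
# growth trajectories.

test_that("the saturated model has zero CH2 amplitude at the n = 2 endpoint", {
  params <- spectral_model_params()
  ax <- srsfa:::.model_axis(params)
  y2 <- srsfa:::.saturated_model_spectrum(ax, 2, params)
  # only the (constant-amplitude) CH3 bands remain
  slope <- function(b, f) if (is.null(b[[f]])) 0 else b[[f]]
  ch3 <- rep(0, length(ax))
  for (b in params$saturated$ch3_bands)
    ch3 <- ch3 + b$amplitude *
      exp(-0.5 * ((ax - b$center - slope(b, "center_slope") * (2 - 6)) /
                    (b$width + slope(b, "width_slope") * (2 - 6)))^2)
  expect_equal(y2, ch3, tolerance = 1e-12)
})

test_that("model references honor the monotone ratio and marker-band rules", {
  lib <- make_reference_spectra()
  r8 <- ch2_ch3_auc_ratio(library_spectrum(lib, "C8:0"))
  r16 <- ch2_ch3_auc_ratio(library_spectrum(lib, "C16:0"))
  expect_gt(r16, r8)
  # unsaturated composite carries > 20% of its mass above 2985 (marker band)
  u <- library_spectrum(lib, "unsat")
  frac <- auc_window(u, c(2985, max(u$wavenumber))) /
    trapz(u$wavenumber, u$intensity)
  expect_gt(frac, 0.20)
  # generation is deterministic
  expect_identical(lib$intensity, make_reference_spectra()$intensity)
  expect_error(make_reference_spectra("C22:0"), "6-20")
})

test_that("sampled AUC ratios agree with the closed-form Gaussian oracle", {
  params <- spectral_model_params()
  gint <- function(c0, w, a, win)
    a * w * sqrt(2 * pi) * (pnorm((win[2] - c0) / w) - pnorm((win[1] - c0) / w))
  slope <- function(b, f) if (is.null(b[[f]])) 0 else b[[f]]
  for (n in c(8, 14, 20)) {
    a2 <- a3 <- 0
    for (b in params$saturated$ch2_bands) {
      c0 <- b$center + slope(b, "center_slope") * (n - 6)
      w <- b$width + slope(b, "width_slope") * (n - 6)
      a2 <- a2 + gint(c0, w, b$amplitude * (n - 2), CH2_WINDOW)
      a3 <- a3 + gint(c0, w, b$amplitude * (n - 2), CH3_WINDOW)
    }
    for (b in params$saturated$ch3_bands) {
      c0 <- b$center + slope(b, "center_slope") * (n - 6)
      w <- b$width + slope(b, "width_slope") * (n - 6)
      a2 <- a2 + gint(c0, w, b$amplitude, CH2_WINDOW)
      a3 <- a3 + gint(c0, w, b$amplitude, CH3_WINDOW)
    }
    sp <- paste0("C", n, ":0")
    r <- ch2_ch3_auc_ratio(library_spectrum(make_reference_spectra(sp), sp))
    expect_equal(r, a2 / a3, tolerance = 5e-3)
  }
})

test_that("GC-MS presets match their strain phenotypes and normalize", {
  short <- make_gcms_profile("short_chain_producer")
  expect_equal(short$species[which.max(short$concentration)], "C8:0")
  mixed <- make_gcms_profile("mixed_producer")
  expect_equal(mixed$species[which.max(mixed$concentration)], "C14:0")
  long <- make_gcms_profile("long_chain_producer")
  top2 <- long$species[order(long$concentration, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("C14:0", "C16:0"))
  for (p in list(short, mixed, long))
    expect_equal(sum(p$concentration), 1, tolerance = 1e-12)
  custom <- make_gcms_profile("custom", species = c("C8:0", "C10:0"),
                              concentration = c(2, 2))
  expect_equal(custom$concentration, c(0.5, 0.5))
  expect_error(make_gcms_profile("custom", species = c("C8:0", "C10:0"),
                                 concentration = c(0, 0)), "positive")
})

test_that("scenes are deterministic, non-overlapping and mass-conserving", {
  prof <- make_gcms_profile("mixed_producer")
  lib <- make_reference_spectra(unsat_weights = prof)
  spec <- scene_spec(nx = 64L, ny = 64L, n_cells = 6L, n_droplets = 3L,
                     seed = 21L)
  sc1 <- make_scene(spec, lib, prof)
  sc2 <- make_scene(spec, lib, prof)
  expect_identical(sc1$stack$data, sc2$stack$data)
  expect_identical(sc1$cell_mask, sc2$cell_mask)
  # cells occupy disjoint pixel sets with positive area
  areas <- table(sc1$cell_mask[sc1$cell_mask > 0])
  expect_equal(length(areas), 6)
  expect_true(all(areas > 0))
  # per-component ground-truth mass equals geometry x composition
  tm <- matrix(sc1$truth, 64 * 64, length(lib$component))
  fa_names <- names(sc1$shares)
  fa_idx <- match(fa_names, lib$component)
  cellv <- as.vector(sc1$cell_mask); dropv <- as.vector(sc1$droplet_mask)
  fa_level <- ifelse(sc1$regions$high_producer, spec$high_fa_level,
                     spec$low_fa_level)
  expected_fa_mass <- sum(sc1$regions$area * fa_level) +
    sum(dropv > 0) * spec$droplet_fa_level
  expect_equal(sum(tm[, fa_idx]), expected_fa_mass, tolerance = 1e-9)
  prot_idx <- which(lib$category == "protein")
  expect_equal(sum(tm[, prot_idx]), sum(cellv > 0) * spec$protein_level,
               tolerance = 1e-9)
  # packing failure raises an error
  expect_error(make_scene(scene_spec(nx = 16L, ny = 16L, n_cells = 200L,
                                     seed = 1L), lib, prof),
               "packing")
})

test_that("at vanishing noise a pure-protein cell shows the protein spectrum", {
  prof <- make_gcms_profile("mixed_producer")
  lib <- make_reference_spectra(c("protein", "C14:0", "unsat"),
                                unsat_weights = prof)
  spec <- scene_spec(nx = 48L, ny = 48L, n_cells = 3L, n_droplets = 0L,
                     high_producer_fraction = 0, low_fa_level = 0,
                     snr = 1e9, seed = 4L)
  sc <- make_scene(spec, lib, prof)
  inside <- which(sc$cell_mask > 0, arr.ind = TRUE)
  i <- inside[1, ]
  expect_equal(sc$stack$data[i[1], i[2], ],
               spec$protein_level * lib$intensity["protein", ],
               tolerance = 1e-6)
})

test_that("noiseless scenes unmix back to their ground truth within 2%", {
  prof <- make_gcms_profile("long_chain_producer")
  lib <- make_reference_spectra(unsat_weights = prof)
  sc <- make_scene(scene_spec(nx = 48L, ny = 48L, n_cells = 4L,
                              n_droplets = 2L, snr = 1e9, seed = 6L),
                   lib, prof)
  maps <- unmix_stack(sc$stack, lib, unmix_config(beta = 1e-10))
  pos <- sc$truth > 1e-6
  rel <- abs(maps$maps[pos] - sc$truth[pos]) / sc$truth[pos]
  expect_lt(max(rel), 0.02)
})

test_that("growth trajectories follow the exponential-with-division model", {
  # no noise, no divisions reachable: exact recovery of mu
  tr <- make_growth_trajectories(n_cells = 3, mu_true = 0.01, noise_sd = 0,
                                 division_length_um = 1e6, frames = 10,
                                 seed = 2)
  rates <- growth_rate(tr)
  expect_equal(rates$mu_per_min, rep(0.01, nrow(rates)), tolerance = 1e-12)
  # zero growth gives constant lengths
  tr0 <- make_growth_trajectories(n_cells = 2, mu_true = 0, noise_sd = 0,
                                  frames = 6, seed = 3)
  expect_true(all(tapply(tr0$length_um, tr0$cell_id,
                         function(x) diff(range(x))) == 0))
  # determinism
  expect_identical(make_growth_trajectories(seed = 5),
                   make_growth_trajectories(seed = 5))
  # noiseless-twin oracle: the twin's rates equal mu exactly, so the noisy
  # batch mean must land within 5% of it (division-free trajectories)
  twin <- make_growth_trajectories(n_cells = 50, mu_true = 0.012,
                                   noise_sd = 0, division_length_um = 1e6,
                                   frames = 30, seed = 10)
  expect_equal(growth_rate(twin)$mu_per_min,
               rep(0.012, 50 * 28), tolerance = 1e-12)
  noisy <- make_growth_trajectories(n_cells = 50, mu_true = 0.012,
                                    noise_sd = 0.02,
                                    division_length_um = 1e6,
                                    frames = 30, seed = 10)
  r <- growth_rate(noisy)
  expect_lt(abs(mean(r$mu_per_min) - 0.012) / 0.012, 0.05)
})
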