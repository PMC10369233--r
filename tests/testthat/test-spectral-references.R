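# Reference spectra: normalization, composites, GC-MS scaling, band ratios
# and the chain-length calibration.

test_that("normalize_spectrum forces unit trapezoidal area and is idempotent", {
  ax <- toy_axis()
  for (h in c(0.3, 1, 17)) {
    box <- normalize_spectrum(srs_spectrum(ax, rep(h, length(ax))))
    expect_equal(box$intensity, rep(1 / 250, length(ax)), tolerance = 1e-12)
  }
  s <- library_spectrum(make_reference_spectra("C16:0"), "C16:0")
  # independent numerical-integration oracle (pracma)
  expect_equal(pracma::trapz(s$wavenumber, s$intensity), 1, tolerance = 1e-9)
  expect_equal(normalize_spectrum(s)$intensity, s$intensity, tolerance = 1e-12)
})

test_that("degenerate spectra are rejected", {
  ax <- toy_axis()
  expect_error(normalize_spectrum(srs_spectrum(ax, rep(0, length(ax)))),
               "non-positive area")
  expect_error(srs_spectrum(ax, rep(NA_real_, length(ax))), "finite")
  expect_error(srs_spectrum(c(1, 1, 2), 1:3), "strictly increasing")
})

test_that("composite unsaturated reference is a convex combination", {
  ax <- toy_axis()
  s1 <- srs_spectrum(ax, exp(-((ax - 2900) / 40)^2))
  s2 <- srs_spectrum(ax, exp(-((ax - 3000) / 20)^2))
  # single nonzero weight returns that normalized spectrum
  one <- composite_unsaturated_reference(list(s1, s2), c(1, 0))
  expect_equal(one$intensity, normalize_spectrum(s1)$intensity,
               tolerance = 1e-12)
  # identical inputs with equal weights are unchanged
  same <- composite_unsaturated_reference(list(s1, s1), c(0.5, 0.5))
  expect_equal(same$intensity, normalize_spectrum(s1)$intensity,
               tolerance = 1e-12)
  # pointwise weighted-sum oracle at 0.25/0.75
  mix <- composite_unsaturated_reference(list(s1, s2), c(0.25, 0.75))
  n1 <- normalize_spectrum(s1)$intensity
  n2 <- normalize_spectrum(s2)$intensity
  expect_equal(mix$intensity, 0.25 * n1 + 0.75 * n2, tolerance = 1e-12)
  # envelope property
  expect_true(all(mix$intensity >= pmin(n1, n2) - 1e-12))
  expect_true(all(mix$intensity <= pmax(n1, n2) + 1e-12))
  # errors
  s3 <- srs_spectrum(ax + 1, s1$intensity)
  expect_error(composite_unsaturated_reference(list(s1, s3), c(1, 1)),
               "axis")
  expect_error(composite_unsaturated_reference(list(s1, s2), c(0, 0)),
               "weights")
})

test_that("GC-MS scaling distributes fatty-acid shares and spares protein", {
  lib <- make_reference_spectra(c("protein", "C8:0", "C14:0", "unsat"))
  prof <- gcms_profile(c("C8:0", "C14:0", "C16:1"), c(30, 60, 10))
  scaled <- scale_references_by_gcms(lib, prof)
  sh <- attr(scaled, "gcms_share")
  # hand-summed share oracle: 30/100, 60/100, 10/100
  expect_equal(unname(sh[c("C8:0", "C14:0", "unsat")]), c(0.3, 0.6, 0.1))
  expect_identical(scaled$intensity["protein", ], lib$intensity["protein", ])
  expect_identical(scaled$component, lib$component)
  expect_equal(scaled$intensity["C8:0", ], 0.3 * lib$intensity["C8:0", ])

  # equal concentrations give equal fatty-acid scaling constants
  prof_eq <- gcms_profile(c("C8:0", "C14:0", "C16:1"), c(5, 5, 5))
  sh_eq <- attr(scale_references_by_gcms(lib, prof_eq), "gcms_share")
  expect_true(all(abs(sh_eq - 1 / 3) < 1e-12))

  # zero-concentration species is retained but scaled to zero
  prof0 <- gcms_profile(c("C8:0", "C14:0", "C16:1"), c(50, 0, 50))
  sc0 <- scale_references_by_gcms(lib, prof0)
  expect_true(all(sc0$intensity["C14:0", ] == 0))
  expect_true("C14:0" %in% sc0$component)

  # saturated library species missing from profile is an error
  expect_error(scale_references_by_gcms(lib, gcms_profile("C8:0", 1)),
               "absent from profile")
  # profile species missing from library: warning, mass reassigned
  prof_x <- gcms_profile(c("C8:0", "C14:0", "C18:0"), c(25, 25, 50))
  expect_warning(sc_x <- scale_references_by_gcms(lib, prof_x), "dropped")
  expect_equal(sum(attr(sc_x, "gcms_share")), 1)
})

test_that("CH2/CH3 AUC ratio matches constant and fine-grid oracles", {
  ax <- toy_axis()
  const <- srs_spectrum(ax, rep(2.5, length(ax)))
  expect_equal(ch2_ch3_auc_ratio(const), 56 / 58, tolerance = 1e-12)
  s <- library_spectrum(make_reference_spectra("C16:0"), "C16:0")
  r <- ch2_ch3_auc_ratio(s)
  # global scaling leaves the ratio unchanged
  s10 <- srs_spectrum(s$wavenumber, 10 * s$intensity)
  expect_equal(ch2_ch3_auc_ratio(s10), r, tolerance = 1e-12)
  # independent fine-grid integration oracle
  r_oracle <- finegrid_auc(s, CH2_WINDOW) / finegrid_auc(s, CH3_WINDOW)
  expect_equal(r, r_oracle, tolerance = 1e-6)
  # near-zero CH3 area yields NaN with a warning
  blank <- srs_spectrum(ax, ifelse(ax < 2900, 1, 0))
  expect_warning(expect_true(is.nan(ch2_ch3_auc_ratio(blank))), "undefined")
})

test_that("AUC ratio increases strictly with chain length across the series", {
  sats <- paste0("C", seq(6, 20, 2), ":0")
  lib <- make_reference_spectra(sats)
  ratios <- vapply(sats, function(s) ch2_ch3_auc_ratio(library_spectrum(lib, s)), 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("calibration matches the closed-form least-squares oracle", {
  # exactly linear ratios give a perfect fit
  ax <- toy_axis()
  cal_lin <- chain_length_calibration(2, 4)
  expect_equal(predict_chain_length(5, cal_lin), 14)
  # 5 noisy points against normal equations
  set.seed(42)
  ns <- c(6, 10, 12, 16, 20)
  specs <- lapply(ns, function(n)
    add_spectrum_noise(library_spectrum(
      make_reference_spectra(paste0("C", n, ":0"), normalize = FALSE),
      paste0("C", n, ":0")), snr = 30))
  cal <- fit_chain_length_calibration(specs, ns)
  ratios <- vapply(specs, ch2_ch3_auc_ratio, 0)
  slope_o <- sum((ratios - mean(ratios)) * (ns - mean(ns))) /
    sum((ratios - mean(ratios))^2)
  int_o <- mean(ns) - slope_o * mean(ratios)
  pred <- slope_o * ratios + int_o
  r2_o <- 1 - sum((ns - pred)^2) / sum((ns - mean(ns))^2)
  expect_equal(cal$slope, slope_o, tolerance = 1e-10)
  expect_equal(cal$intercept, int_o, tolerance = 1e-10)
  expect_equal(cal$r_squared, r2_o, tolerance = 1e-10)
})

test_that("calibration preconditions are enforced", {
  lib <- make_reference_spectra(c("C8:0", "C14:0"))
  s8 <- library_spectrum(lib, "C8:0")
  s14 <- library_spectrum(lib, "C14:0")
  expect_error(fit_chain_length_calibration(list(s8, s14), c(8, 14)),
               "3 distinct")
  expect_error(fit_chain_length_calibration(list(s8, s8, s8), c(8, 8, 8)),
               "3 distinct")
})

test_that("noiseless standards calibrate to near-perfect linearity", {
  ns <- seq(6, 20, 2)
  lib <- make_reference_spectra(paste0("C", ns, ":0"))
  specs <- lapply(paste0("C", ns, ":0"), library_spectrum, lib = lib)
  cal <- fit_chain_length_calibration(specs, ns)
  expect_gte(cal$r_squared, 0.999)
  pred <- predict_chain_length(vapply(specs, ch2_ch3_auc_ratio, 0), cal)
  expect_true(all(abs(pred - ns) <= 0.25))
})

test_that("predictions clip to the standards span with a flag", {
  cal <- chain_length_calibration(2, 4)
  p <- predict_chain_length(c(0, 5, 100), cal)
  expect_equal(as.numeric(p), c(6, 14, 20))
  expect_equal(attr(p, "out_of_range"), c(1L, 3L))
  expect_equal(as.numeric(predict_chain_length(100, cal, clip = FALSE)), 204)
})
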