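# Readers and writers for the on-disk formats: hyperspectral stacks
# (multi-page TIFF + JSON wavenumber sidecar), reference and GC-MS CSVs,
# label masks, region tables, trajectories, calibrations and configs.
#
# TIFF dialect: 32-bit samples scaled to [0, 1] on write with the scale
# factor recorded in the sidecar/manifest, one page per wavenumber; masks
# are 16-bit integer. Coordinates are row-major with origin top-left.

#' Write a hyperspectral stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit page per wavenumber. Intensities are stored scaled to [0, 1];
#' the scale factor is written to the sidecar
#' (`{"wavenumbers_cm1": [...], "intensity_scale": s}`) and restored on
#' read, so a round trip is lossless to float32 precision.
#'
#' @param stack An [srs_stack()].
#' @param tiff_path,sidecar_path Output paths.
#' @return Invisibly, the sidecar list.
#' @export
write_hyperstack <- function(stack, tiff_path, sidecar_path) {
  stopifnot(inherits(stack, "srs_stack"))
  sc <- max(abs(stack$data), 1e-300)
  pages <- lapply(seq_along(stack$wavenumber),
                  function(i) pmin(pmax(stack$data[, , i] / sc, 0), 1))
  neg <- any(stack$data < 0)
  if (neg)
    warning("negative intensities clipped to 0 on write", call. = FALSE)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32, compression = "none")
  sidecar <- list(wavenumbers_cm1 = stack$wavenumber, intensity_scale = sc)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a hyperspectral stack from multi-page TIFF plus JSON sidecar
#'
#' Validates that the page count matches the sidecar wavenumber count. A
#' non-monotone axis is sorted (pages reordered) with a warning.
#'
#' @param tiff_path,sidecar_path Input paths.
#' @return An [srs_stack()].
#' @export
read_hyperstack <- function(tiff_path, sidecar_path) {
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  w <- as.numeric(sidecar$wavenumbers_cm1)
  sc <- if (!is.null(sidecar$intensity_scale)) sidecar$intensity_scale else 1
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != length(w))
    stop(sprintf("page count (%d) does not match sidecar wavenumber count (%d)",
                 length(pages), length(w)), call. = FALSE)
  if (any(diff(w) <= 0)) {
    warning("sidecar wavenumbers not strictly increasing; sorting pages",
            call. = FALSE)
    o <- order(w)
    w <- w[o]
    pages <- pages[o]
  }
  d <- dim(pages[[1]])
  data <- array(0, c(d[1], d[2], length(w)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]] * sc
  srs_stack(w, data)
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' @param mask Integer matrix of region labels (0 = background, < 65536).
#' @param path File path.
#' @return `read_mask_tiff` returns an integer matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask < 65536), all(mask == round(mask)))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write / read a reference library CSV
#'
#' Format: first column `wavenumber_cm1`, one column per component named
#' `protein`, `Cn.0`-style species (written as `Cn:0`) or `unsat`; UTF-8
#' with a header row.
#'
#' @param lib A [reference_library()].
#' @param path File path.
#' @return `read_reference_csv` returns a [reference_library()].
#' @export
write_reference_csv <- function(lib, path) {
  stopifnot(inherits(lib, "srs_library"))
  df <- data.frame(wavenumber_cm1 = lib$wavenumber, t(lib$intensity),
                   check.names = FALSE)
  names(df) <- c("wavenumber_cm1", lib$component)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm1")
    stop("first column must be 'wavenumber_cm1'", call. = FALSE)
  comps <- names(df)[-1]
  if (length(comps) == 0) stop("no component columns", call. = FALSE)
  reference_library(df$wavenumber_cm1, t(as.matrix(df[, -1, drop = FALSE])),
                    comps)
}

#' Write / read a GC-MS composition CSV
#'
#' Columns `species` (`Cn:u` labels) and `concentration`; lines starting
#' with `#` are comments (the writer emits a units header comment).
#' Malformed species labels are rejected with their row numbers.
#'
#' @param profile A [gcms_profile()].
#' @param path File path.
#' @param units Unit string recorded in the header comment.
#' @return `read_gcms_csv` returns a [gcms_profile()].
#' @export
write_gcms_csv <- function(profile, path, units = "relative fraction") {
  stopifnot(inherits(profile, "gcms_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# concentration units: %s", units), con)
  utils::write.csv(profile[, c("species", "concentration")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_gcms_csv
#' @export
read_gcms_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("species", "concentration") %in% names(df)))
    stop("GC-MS CSV needs columns 'species' and 'concentration'", call. = FALSE)
  ok <- grepl("^C[0-9]+:[0-9]+$", df$species)
  if (any(!ok))
    stop("malformed species label(s) at data row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(df$species[!ok], collapse = ", "), call. = FALSE)
  tryCatch(gcms_profile(df$species, df$concentration),
           error = function(e) stop("invalid GC-MS CSV: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a region quantification table as CSV
#' @param table A [quantify_regions()] result.
#' @param path File path.
#' @export
write_region_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write / read cell-length trajectories CSV
#'
#' Columns `cell_id`, `frame`, `time_min`, `length_um` and optionally
#' `parent_id`.
#'
#' @param traj Trajectory data frame.
#' @param path File path.
#' @return `read_trajectories_csv` returns the data frame.
#' @export
write_trajectories_csv <- function(traj, path) {
  stopifnot(all(c("cell_id", "time_min", "length_um") %in% names(traj)))
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "time_min", "length_um")
  if (!all(need %in% names(df)))
    stop("trajectories CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$length_um)) || any(df$length_um <= 0))
    stop("lengths must be positive at data row(s) ",
         paste(which(!(df$length_um > 0)), collapse = ", "), call. = FALSE)
  df
}

#' Write / read a chain-length calibration as JSON
#' @param cal A [chain_length_calibration()].
#' @param path File path.
#' @return `read_calibration_json` returns the calibration.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "chain_length_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chain_length_calibration(x$slope, x$intercept, x$r_squared,
                           x$ch2_window, x$ch3_window)
}

#' Write a chain-length map as 32-bit TIFF (NA for undefined pixels)
#'
#' Undefined pixels are stored as 0 with a parallel validity page; the
#' companion JSON records the value scale.
#'
#' @param clm Matrix from [chain_length_map()].
#' @param path TIFF path; a `.json` sidecar is written alongside.
#' @export
write_chain_length_map <- function(clm, path) {
  sc <- 20
  vals <- ifelse(is.finite(clm), clm / sc, 0)
  valid <- ifelse(is.finite(clm), 1, 0)
  tiff::writeTIFF(list(vals, valid), path, bits.per.sample = 32,
                  compression = "none")
  jsonlite::write_json(list(value_scale = sc, pages = c("value", "valid")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a pipeline configuration YAML
#'
#' Single YAML file holding paths, solver settings, spectral windows,
#' thresholds, bins, quantile fraction, pixel size and seed; CLI flags
#' override these values.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$high_producer_fraction)) {
    f <- cfg$high_producer_fraction
    if (f <= 0 || f >= 1)
      stop("high_producer_fraction must be in (0, 1)", call. = FALSE)
  }
  cfg
}

#' Write / read a chemical-maps directory
#'
#' One 32-bit TIFF per component (`<component>.tif`, `:` replaced by `_` in
#' file names), optional `residual.tif` pages, and a `manifest.json`
#' recording components, categories, chain lengths, reference areas, the
#' wavenumber axis, intensity scales and the unmixing configuration.
#'
#' @param maps A [unmix_stack()] result.
#' @param dir Output directory (created if needed).
#' @param extra Named list merged into the manifest (e.g. seed, library
#'   hash).
#' @return `read_chemical_maps` returns a `chemical_maps` object.
#' @export
write_chemical_maps <- function(maps, dir, extra = list()) {
  stopifnot(inherits(maps, "chemical_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- numeric(length(maps$component))
  for (k in seq_along(maps$component)) {
    m <- maps$maps[, , k]
    scales[k] <- max(abs(m), 1e-300)
    tiff::writeTIFF(pmin(pmax(m / scales[k], 0), 1),
                    file.path(dir, paste0(gsub(":", "_", maps$component[k]), ".tif")),
                    bits.per.sample = 32, compression = "none")
  }
  if (!is.null(maps$residual)) {
    rs <- max(abs(maps$residual), 1e-300)
    pages <- lapply(seq_len(dim(maps$residual)[3]),
                    function(i) (maps$residual[, , i] / rs + 1) / 2)
    tiff::writeTIFF(pages, file.path(dir, "residual.tif"),
                    bits.per.sample = 32, compression = "none")
  } else rs <- NULL
  manifest <- c(list(component = maps$component, category = maps$category,
                     chain_length = maps$chain_length,
                     ref_auc = as.list(maps$ref_auc),
                     wavenumber = maps$wavenumber,
                     map_scale = as.list(stats::setNames(scales, maps$component)),
                     residual_scale = rs,
                     config = unclass(maps$config)), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_chemical_maps
#' @export
read_chemical_maps <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  comps <- mf$component
  first <- tiff::readTIFF(file.path(dir, paste0(gsub(":", "_", comps[1]), ".tif")))
  d <- dim(first)
  arr <- array(0, c(d[1], d[2], length(comps)))
  for (k in seq_along(comps)) {
    m <- tiff::readTIFF(file.path(dir, paste0(gsub(":", "_", comps[k]), ".tif")))
    arr[, , k] <- m * mf$map_scale[[comps[k]]]
  }
  residual <- NULL
  rpath <- file.path(dir, "residual.tif")
  if (file.exists(rpath) && !is.null(mf$residual_scale)) {
    pages <- tiff::readTIFF(rpath, all = TRUE)
    residual <- array(0, c(d[1], d[2], length(pages)))
    for (i in seq_along(pages))
      residual[, , i] <- (pages[[i]] * 2 - 1) * mf$residual_scale
  }
  cfg <- unmix_config(beta = mf$config$beta, nonnegative = mf$config$nonnegative,
                      normalize = mf$config$normalize,
                      max_iterations = mf$config$max_iterations,
                      tolerance = mf$config$tolerance)
  structure(list(maps = arr, component = comps, category = mf$category,
                 chain_length = ifelse(is.na(mf$chain_length) |
                                         mf$chain_length < 0,
                                       NA_integer_,
                                       as.integer(mf$chain_length)),
                 ref_auc = stats::setNames(unlist(mf$ref_auc), comps),
                 wavenumber = mf$wavenumber, residual = residual,
                 config = cfg),
            class = "chemical_maps")
}
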