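# Single-cell / colony / droplet quantification from label masks, high-producer
# classification, and growth rates from cell-length trajectories.

#' Quantify chemical maps over labeled regions
#'
#' Sums protein and fatty-acid signal over each labeled region of an integer
#' mask (0 = background, excluded). Both normalizations are always reported:
#' fatty acid per cell area (single-cell production; cells lie side by side)
#' and fatty acid per protein (microcolony production; accounts for cells
#' growing on top of each other). `mode` selects which is the headline metric
#' used downstream by [classify_high_producers()].
#'
#' @param maps A [unmix_stack()] result.
#' @param mask Integer Nx x Ny label matrix; region ids need not be
#'   contiguous.
#' @param mode `"per_area"` (default) or `"per_protein"`.
#' @param fa_weights Passed to [combined_fatty_acid_map()] (`"none"` or
#'   `"auc"`).
#' @return Data frame of class `region_table`: `region`, `area`,
#'   `protein_total`, `fa_total`, `fa_per_area`, `fa_per_protein`.
#'   Regions with zero protein get `NA` in `fa_per_protein`.
#' @export
quantify_regions <- function(maps, mask, mode = c("per_area", "per_protein"),
                             fa_weights = "none") {
  stopifnot(inherits(maps, "chemical_maps"))
  mode <- match.arg(mode)
  d <- dim(maps$maps)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape must match maps", call. = FALSE)
  ids <- sort(unique(as.vector(mask)))
  ids <- ids[ids > 0]
  if (length(ids) == 0) stop("mask has no labeled regions", call. = FALSE)
  fa_map <- as.vector(combined_fatty_acid_map(maps, weights = fa_weights))
  prot_idx <- which(maps$category == "protein")
  prot_map <- if (length(prot_idx)) .map_matrix(maps)[, prot_idx] else
    rep(NA_real_, d[1] * d[2])
  mv <- as.vector(mask)
  f <- factor(mv[mv > 0], levels = ids)
  area <- as.vector(table(f))
  fa_total <- as.vector(tapply(fa_map[mv > 0], f, sum))
  protein_total <- as.vector(tapply(prot_map[mv > 0], f, sum))
  out <- data.frame(region = ids, area = area,
                    protein_total = protein_total, fa_total = fa_total,
                    fa_per_area = fa_total / area,
                    fa_per_protein = ifelse(is.na(protein_total) |
                                              protein_total <= 0,
                                            NA_real_,
                                            fa_total / protein_total))
  if (any(is.na(out$fa_per_protein)) && mode == "per_protein")
    warning("regions with zero protein flagged NA in fa_per_protein",
            call. = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("region_table", "data.frame")
  out
}

#' Flag high-producer regions
#'
#' High producers are the top `fraction` of regions by the headline
#' production metric (default: top 15% by fatty acid per area). The cut is
#' the empirical `1 - fraction` quantile with linear interpolation
#' (`stats::quantile` type 7); ties at the quantile are included. If every
#' value is identical all regions are flagged, with a warning.
#'
#' @param table A [quantify_regions()] result (or data frame with the
#'   metric column).
#' @param fraction Top fraction to flag, in (0, 1). Default 0.15.
#' @param metric Column to rank by; default follows the table's `mode`
#'   attribute (`fa_per_area` or `fa_per_protein`).
#' @return The table with a logical `high_producer` column appended.
#' @export
classify_high_producers <- function(table, fraction = 0.15, metric = NULL) {
  stopifnot(is.data.frame(table), fraction > 0, fraction < 1)
  if (is.null(metric))
    metric <- if (identical(attr(table, "mode"), "per_protein"))
      "fa_per_protein" else "fa_per_area"
  v <- table[[metric]]
  if (is.null(v) || any(!is.finite(v)))
    stop("metric column missing or contains non-finite values", call. = FALSE)
  if (length(unique(v)) == 1) {
    warning("degenerate production distribution: all regions flagged",
            call. = FALSE)
    table$high_producer <- rep(TRUE, length(v))
    return(table)
  }
  thr <- stats::quantile(v, probs = 1 - fraction, type = 7, names = FALSE)
  table$high_producer <- v >= thr
  table
}

#' Per-frame growth rates from a cell-length trajectory
#'
#' Centered logarithmic derivative of cell length,
#' `mu_k = ln(L_{k+1} / L_{k-1}) / (2 dt)`, defined for interior frames
#' only (no extrapolation at the endpoints). Exact for exponential growth.
#' Frames must be uniformly spaced. With `mask_divisions = TRUE`, rates at
#' frames within one frame of a division event (length drop > 30% between
#' consecutive frames) are set `NA`, since the centered difference spans
#' the halving.
#'
#' @param traj Data frame with columns `time_min` and `length_um` (one
#'   cell), optionally `cell_id` to process several cells at once.
#' @param spacing_tol Relative tolerance on frame-spacing uniformity.
#' @param mask_divisions Mask rates adjacent to divisions? Default `FALSE`
#'   (raw rates, with division frames visible as negative spikes).
#' @return Data frame `cell_id`, `frame`, `time_min`, `mu_per_min`.
#' @export
growth_rate <- function(traj, spacing_tol = 1e-6, mask_divisions = FALSE) {
  stopifnot(is.data.frame(traj),
            all(c("time_min", "length_um") %in% names(traj)))
  if (!"cell_id" %in% names(traj)) traj$cell_id <- 1L
  out <- lapply(split(traj, traj$cell_id), function(tr) {
    tr <- tr[order(tr$time_min), ]
    t <- tr$time_min
    L <- tr$length_um
    if (length(t) < 3)
      stop("need >= 3 frames per cell", call. = FALSE)
    if (any(L <= 0)) stop("cell lengths must be positive", call. = FALSE)
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > spacing_tol * abs(dt[1]))
      stop("frames are not uniformly spaced", call. = FALSE)
    k <- 2:(length(t) - 1)
    mu <- log(L[k + 1] / L[k - 1]) / (2 * dt[1])
    if (mask_divisions) {
      div <- which(diff(L) / L[-length(L)] < -0.30)  # drop between frame i, i+1
      near <- unique(unlist(lapply(div, function(i) (i - 1):(i + 2))))
      mu[(k %in% near)] <- NA_real_
    }
    data.frame(cell_id = tr$cell_id[1], frame = k, time_min = t[k],
               mu_per_min = mu)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Protein and fatty-acid totals of colonies over time
#'
#' Applies [quantify_regions()] frame by frame over a time-lapse of chemical
#' maps and colony masks, returning a tidy series. Timepoints with a missing
#' mask are recorded as `NA` rows, never interpolated.
#'
#' @param maps_list List of [unmix_stack()] results, one per timepoint.
#' @param masks_list List of label masks aligned to `maps_list` (entries may
#'   be `NULL` for missing timepoints).
#' @param times Numeric timestamps (e.g. hours), one per timepoint.
#' @param fa_weights Passed to [quantify_regions()].
#' @return Data frame `time`, `region`, `area`, `protein_total`, `fa_total`,
#'   `fa_per_protein`.
#' @export
colony_time_series <- function(maps_list, masks_list, times,
                               fa_weights = "none") {
  stopifnot(length(maps_list) >= 2,
            length(masks_list) == length(maps_list),
            length(times) == length(maps_list))
  rows <- lapply(seq_along(times), function(i) {
    if (is.null(masks_list[[i]]))
      return(data.frame(time = times[i], region = NA_integer_,
                        area = NA_integer_, protein_total = NA_real_,
                        fa_total = NA_real_, fa_per_protein = NA_real_))
    q <- quantify_regions(maps_list[[i]], masks_list[[i]],
                          mode = "per_protein", fa_weights = fa_weights)
    data.frame(time = times[i], region = q$region, area = q$area,
               protein_total = q$protein_total, fa_total = q$fa_total,
               fa_per_protein = q$fa_per_protein)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
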