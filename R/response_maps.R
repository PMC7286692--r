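#' @title Image-registered scene response maps
#'
#' @description
#' The core computation: a scene response map assigns to each *image*
#' coordinate the firing rate observed when that part of the image lay over
#' the receptive-field centre. With grid position `g` (the image-centre
#' offset from fixation) and RF centre `r`, the image coordinate over the RF
#' is `c = r - g`; trial repetitions are averaged per position.
#'
#' @name response_maps
NULL

#' Build a scene response map for one channel or the population
#'
#' @param spikes An `fm_spikes`.
#' @param protocol An `fm_protocol` whose grid is centred on the RF centre.
#' @param scene_id Scene to map.
#' @param rf_center RF centre `c(x, y)` in degrees from fixation (from the
#'   mapping stage).
#' @param channel Channel index, or `"population"` for the across-channel
#'   mean.
#' @param window_ms Analysis window after onset (default `c(100, 250)`; use
#'   `c(150, 300)` for the slower-latency profile).
#' @return Object of class `"fm_map"`: `x`, `y` (image coordinates, deg),
#'   `values` (matrix rows = y, cols = x, mean rate in Hz), plus metadata.
#' @export
build_scene_response_map <- function(spikes, protocol, scene_id, rf_center,
                                     channel = "population",
                                     window_ms = c(100, 250)) {
  ev <- protocol$events[protocol$events$scene_id == scene_id, ]
  if (nrow(ev) == 0)
    fm_error("facemap_unknown_scene",
             sprintf("scene '%s' does not occur in the protocol", scene_id))
  cx <- rf_center[1] - ev$grid_x
  cy <- rf_center[2] - ev$grid_y
  chans <- if (identical(channel, "population")) seq_len(spikes$n_channels)
           else channel
  rate <- rep(0, nrow(ev))
  for (ch in chans)
    rate <- rate + window_counts(spikes$channels[[ch]], ev$onset_ms,
                                 window_ms) / diff(window_ms) * 1000
  rate <- rate / length(chans)
  xs <- sort(unique(round(cx, 9))); ys <- sort(unique(round(cy, 9)))
  vals <- tapply(rate, list(factor(round(cy, 9), ys), factor(round(cx, 9), xs)),
                 mean)
  vals <- matrix(as.numeric(vals), length(ys), length(xs),
                 dimnames = list(ys, xs))
  structure(list(x = xs, y = ys, values = vals, scene_id = scene_id,
                 channel = channel, window_ms = window_ms,
                 spacing_deg = protocol$spacing_deg, rf_center = rf_center),
            class = "fm_map")
}

#' Bilinear interpolation of a map between grid nodes
#'
#' Values at the nodes are preserved exactly; the dense raster never extends
#' beyond the outer nodes (no extrapolation), so interpolated values stay
#' within the node range.
#'
#' @param map An `fm_map` (or `fm_grid`).
#' @param px_per_deg Dense resolution, pixels per degree.
#' @return The map with `x`, `y`, `values` replaced by the dense versions and
#'   `dense = TRUE`.
#' @export
interpolate_map <- function(map, px_per_deg = 4) {
  dense_axis <- function(a) {
    n <- max(2L, round((max(a) - min(a)) * px_per_deg) + 1L)
    seq(min(a), max(a), length.out = n)
  }
  xd <- dense_axis(map$x); yd <- dense_axis(map$y)
  W <- function(target, nodes) {
    # weight matrix: rows = dense points, cols = nodes; exact 0/1 at nodes
    i <- findInterval(target, nodes, all.inside = TRUE)
    t <- (target - nodes[i]) / (nodes[i + 1] - nodes[i])
    M <- matrix(0, length(target), length(nodes))
    M[cbind(seq_along(target), i)] <- 1 - t
    M[cbind(seq_along(target), i + 1)] <- M[cbind(seq_along(target), i + 1)] + t
    M
  }
  dense <- W(yd, map$y) %*% map$values %*% t(W(xd, map$x))
  out <- map
  out$x <- xd; out$y <- yd
  out$values <- dense
  out$dense <- TRUE
  out
}

#' Percentile display scaling of a map
#'
#' Affine rescale of the map values to `[0, 1]`, clipping at the per-image
#' 0.5 and 99.5 percentiles (computed on the map as given — normally the
#' dense, interpolated rendering). A constant map collapses to a single
#' mid-scale level without division by zero.
#'
#' @param map An `fm_map`.
#' @param probs Clipping percentiles (default `c(0.005, 0.995)`).
#' @return The map with values rescaled into `[0, 1]` and an attribute
#'   `scaling_bounds`.
#' @export
scale_map <- function(map, probs = c(0.005, 0.995)) {
  v <- map$values
  qs <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
  out <- map
  if (diff(qs) == 0) {
    out$values <- matrix(0.5, nrow(v), ncol(v), dimnames = dimnames(v))
  } else {
    out$values <- pmin(pmax((v - qs[1]) / (qs[2] - qs[1]), 0), 1)
  }
  out$scaling_bounds <- qs
  out
}

#' Temporal sequence of response maps
#'
#' One map per half-open time bin `[t, t + bin_ms)` between `range_ms[1]` and
#' `range_ms[2]` after onset.
#'
#' @inheritParams build_scene_response_map
#' @param bin_ms Bin width (default 40).
#' @param range_ms Overall range (default `c(50, 250)`).
#' @return List of `fm_map`s, named by bin start time.
#' @export
temporal_maps <- function(spikes, protocol, scene_id, rf_center,
                          channel = "population", bin_ms = 40,
                          range_ms = c(50, 250)) {
  starts <- seq(range_ms[1], range_ms[2] - bin_ms, by = bin_ms)
  maps <- lapply(starts, function(t0)
    build_scene_response_map(spikes, protocol, scene_id, rf_center,
                             channel = channel, window_ms = c(t0, t0 + bin_ms)))
  names(maps) <- starts
  maps
}

#' Pointwise mean of response maps across channels
#'
#' @param maps List of `fm_map`s on identical grids (e.g. one per responsive
#'   channel).
#' @return An `fm_map` labelled `"population"`.
#' @export
population_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  x0 <- maps[[1]]$x; y0 <- maps[[1]]$y
  for (m in maps)
    if (!isTRUE(all.equal(m$x, x0)) || !isTRUE(all.equal(m$y, y0)))
      fm_error("facemap_grid_mismatch", "maps are on different grids")
  arr <- simplify2array(lapply(maps, `[[`, "values"))
  out <- maps[[1]]
  out$values <- apply(arr, c(1, 2), mean)
  out$channel <- "population"
  out
}

#' Composite best-orientation map
#'
#' For maps of the same body at several orientations, reports at each grid
#' point the orientation with the maximal response, masking points where no
#' orientation exceeds baseline. Under finite sampling the unmasking decision
#' takes a maximum over all orientation maps, so "above baseline" is
#' operationalised as exceeding `baseline_hz + z * se_hz` with `z` the
#' one-sided normal quantile at `alpha` Bonferroni-corrected across the
#' orientations; with the default `se_hz = 0` this reduces to the exact
#' at-or-below-baseline mask whatever `alpha`.
#'
#' @param maps Named list of `fm_map`s; names are orientations in degrees.
#' @param baseline_hz Baseline firing rate.
#' @param se_hz Standard error of a map value (0 for noiseless input).
#' @param alpha Per-point false-unmasking probability across orientations
#'   (default 0.01).
#' @return List with `orientation` (numeric matrix of winning orientations,
#'   degrees; ties go to the first listed orientation), `masked` (logical
#'   matrix, `TRUE` where all orientations are at or below baseline), and the
#'   grid axes.
#' @export
composite_orientation_map <- function(maps, baseline_hz, se_hz = 0,
                                      alpha = 0.01) {
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  x0 <- maps[[1]]$x; y0 <- maps[[1]]$y
  for (m in maps)
    if (!isTRUE(all.equal(m$x, x0)) || !isTRUE(all.equal(m$y, y0)))
      fm_error("facemap_grid_mismatch",
               "orientation maps are on mismatched grids")
  arr <- simplify2array(lapply(maps, `[[`, "values"))
  orients <- as.numeric(names(maps))
  win <- apply(arr, c(1, 2), which.max)
  mx <- apply(arr, c(1, 2), max)
  z <- if (se_hz > 0) stats::qnorm(1 - alpha / length(maps)) else 0
  masked <- mx <= baseline_hz + z * se_hz
  orientation <- matrix(orients[win], nrow(win), ncol(win))
  orientation[masked] <- NA_real_
  list(orientation = orientation, masked = masked, x = x0, y = y0,
       baseline_hz = baseline_hz, se_hz = se_hz)
}

#' Noise-free oracle response map from the deterministic rate model
#'
#' Integrates [drive_rate()] over the analysis window at every grid position
#' and registers the result in image coordinates exactly as
#' [build_scene_response_map()] does. Used as the independent reference for
#' pipeline fidelity checks.
#'
#' @param cell An `fm_cell`.
#' @param scene An `fm_scene`.
#' @param protocol An `fm_protocol` (its grid defines the positions).
#' @param window_ms Analysis window.
#' @return An `fm_map` of window-mean rates.
#' @export
oracle_response_map <- function(cell, scene, protocol, window_ms = c(100, 250)) {
  gx <- protocol$grid_x; gy <- protocol$grid_y
  r <- cell$rf_center_deg
  tt <- seq(window_ms[1], window_ms[2] - 1) + 0.5
  vals <- matrix(NA_real_, length(gy), length(gx))
  for (i in seq_along(gy)) for (j in seq_along(gx))
    vals[i, j] <- mean(drive_rate(cell, scene, c(gx[j], gy[i]), tt))
  # register: image coordinate c = r - g; flipping both axes reverses order
  xs <- rev(r[1] - gx); ys <- rev(r[2] - gy)
  vals <- vals[rev(seq_along(gy)), rev(seq_along(gx)), drop = FALSE]
  dimnames(vals) <- list(ys, xs)
  structure(list(x = xs, y = ys, values = vals, scene_id = scene$scene_id,
                 channel = "oracle", window_ms = window_ms,
                 spacing_deg = protocol$spacing_deg, rf_center = r),
            class = "fm_map")
}

#' Write a map (or grid) as a long-format CSV
#' @param map An `fm_map` or `fm_grid`.
#' @param path Output path.
#' @param extra Named list of constant columns to prepend (e.g. scene id).
#' @export
write_map_csv <- function(map, path, extra = list()) {
  df <- data.frame(x = rep(map$x, each = length(map$y)),
                   y = rep(map$y, times = length(map$x)),
                   value = as.vector(map$values))
  for (nm in rev(names(extra))) df <- cbind(setNames(data.frame(extra[[nm]]), nm), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
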