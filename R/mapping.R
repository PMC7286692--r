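#' @title Receptive-field estimation and category selectivity
#' @name mapping
NULL

#' Baseline-subtracted probe response grid for one channel
#'
#' For every probe position, the mean over repetitions of the evoked rate
#' (spike count over `window_evoked` after onset) minus the baseline rate
#' (count over `window_baseline`), in Hz. Positions never probed are flagged
#' `NA` (missing), not silently zero.
#'
#' @param spikes An `fm_spikes`.
#' @param protocol The probe `fm_protocol`.
#' @param channel Channel index.
#' @param window_evoked Evoked window, ms after onset (default `c(80, 250)`).
#' @param window_baseline Baseline window (default `c(0, 30)`).
#' @param pool_baseline The baseline window closes before the earliest
#'   response latency, so the baseline rate does not depend on probe
#'   position; pooling its estimate across all presentations (the default)
#'   estimates the same quantity with far less variance. Set `FALSE` for
#'   strictly per-position subtraction.
#' @return Object of class `"fm_grid"`: list with `x`, `y` (degrees),
#'   `values` (matrix, rows indexed by `y`, columns by `x`), `n_reps`.
#' @export
probe_response_grid <- function(spikes, protocol, channel,
                                window_evoked = c(80, 250),
                                window_baseline = c(0, 30),
                                pool_baseline = TRUE) {
  ev <- protocol$events
  st <- spikes$channels[[channel]]
  ce <- window_counts(st, ev$onset_ms, window_evoked) /
    diff(window_evoked) * 1000
  cb <- window_counts(st, ev$onset_ms, window_baseline) /
    diff(window_baseline) * 1000
  if (pool_baseline) cb <- rep(mean(cb), length(cb))
  resp <- ce - cb
  xs <- sort(unique(ev$grid_x)); ys <- sort(unique(ev$grid_y))
  vals <- matrix(NA_real_, length(ys), length(xs),
                 dimnames = list(ys, xs))
  nrep <- vals
  agg <- tapply(resp, list(factor(ev$grid_y, ys), factor(ev$grid_x, xs)),
                mean)
  cnt <- tapply(resp, list(factor(ev$grid_y, ys), factor(ev$grid_x, xs)),
                length)
  vals[] <- agg
  nrep[] <- cnt
  structure(list(x = xs, y = ys, values = vals, n_reps = nrep,
                 window_evoked = window_evoked,
                 window_baseline = window_baseline,
                 channel = channel),
            class = "fm_grid")
}

#' Fit a 2D Gaussian to a response grid
#'
#' Least-squares fit of `offset + amplitude * exp(-dx^2/(2 sx^2) -
#' dy^2/(2 sy^2))` by Levenberg-Marquardt with multi-start initialisation at
#' the grid argmax (and its runner-up). Missing grid positions are excluded
#' from the loss. sigma is optimised on the log scale, guaranteeing
#' positivity.
#'
#' @param grid An `fm_grid` with at least 6 non-missing points and positive
#'   dynamic range.
#' @param shared_sigma Fit a single sigma for both axes instead of
#'   independent widths (default `FALSE`).
#' @return Object of class `"fm_rf_fit"`: `centroid_deg`, `sigma_deg`
#'   (length 2), `amplitude_hz`, `offset_hz`, `goodness` (fraction of
#'   variance explained).
#' @export
fit_rf_gaussian <- function(grid, shared_sigma = FALSE) {
  ok <- is.finite(grid$values)
  if (sum(ok) < 6)
    fm_error("facemap_insufficient_grid",
             "RF fit requires at least 6 non-missing grid points")
  px <- rep(grid$x, each = length(grid$y))[as.vector(ok)]
  py <- rep(grid$y, times = length(grid$x))[as.vector(ok)]
  v <- grid$values[ok]
  if (diff(range(v)) <= 0)
    fm_error("facemap_degenerate_fit",
             "response grid is flat; 2D Gaussian fit is degenerate")
  spacing <- min(diff(sort(unique(grid$x))))
  model <- function(p) {
    sx <- exp(p[3]); sy <- if (shared_sigma) sx else exp(p[4])
    p[5 + !shared_sigma] +
      p[4 + !shared_sigma] * exp(-(px - p[1])^2 / (2 * sx^2) -
                                   (py - p[2])^2 / (2 * sy^2))
  }
  resid <- function(p) v - model(p)
  starts <- order(v, decreasing = TRUE)[1:2]
  best <- NULL
  for (s in starts) {
    p0 <- c(px[s], py[s], log(spacing))
    if (!shared_sigma) p0 <- c(p0, log(spacing))
    p0 <- c(p0, max(v) - min(v), min(v))
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    fm_error("facemap_degenerate_fit", "2D Gaussian fit failed to converge")
  p <- best$par
  sx <- exp(p[3]); sy <- if (shared_sigma) sx else exp(p[4])
  centroid <- p[1:2]
  lim_lo <- c(min(grid$x), min(grid$y)) - spacing
  lim_hi <- c(max(grid$x), max(grid$y)) + spacing
  if (any(centroid < lim_lo | centroid > lim_hi))
    fm_error("facemap_degenerate_fit",
             "fitted centroid lies outside the probed grid")
  ss_res <- best$deviance
  ss_tot <- sum((v - mean(v))^2)
  structure(list(centroid_deg = centroid, sigma_deg = c(sx, sy),
                 amplitude_hz = p[4 + !shared_sigma],
                 offset_hz = p[5 + !shared_sigma],
                 goodness = 1 - ss_res / ss_tot),
            class = "fm_rf_fit")
}

#' Population receptive field: pointwise mean over channel grids
#'
#' @param grids List of `fm_grid` objects on identical coordinates.
#' @return An `fm_grid` whose values are the across-channel mean (missing
#'   positions ignored pointwise).
#' @export
population_rf <- function(grids) {
  stopifnot(length(grids) >= 1)
  x0 <- grids[[1]]$x; y0 <- grids[[1]]$y
  for (g in grids)
    if (!isTRUE(all.equal(g$x, x0)) || !isTRUE(all.equal(g$y, y0)))
      fm_error("facemap_grid_mismatch", "grids are on different coordinates")
  arr <- simplify2array(lapply(grids, `[[`, "values"))
  vals <- apply(arr, c(1, 2), function(z) mean(z, na.rm = TRUE))
  vals[!is.finite(vals)] <- NA_real_
  out <- grids[[1]]
  out$values <- vals
  out$channel <- "population"
  out
}

#' Category selectivity index
#'
#' `(r1 - r2) / (r1 + r2)`, bounded in `[-1, 1]` for nonnegative responses.
#' Channels with negative responses are excluded upstream (see
#' [category_selectivity()]).
#'
#' @param r1,r2 Mean responses (Hz) to the two categories.
#' @return The index.
#' @export
selectivity_index <- function(r1, r2) {
  if (r1 + r2 == 0)
    fm_error("facemap_undefined_index",
             "selectivity index undefined when r1 + r2 == 0")
  (r1 - r2) / (r1 + r2)
}

#' Windowed category tuning of every channel
#'
#' Baseline-subtracted mean responses per channel and category, plus
#' per-category population PSTHs, for a protocol in which single-category
#' images are presented within the activating region.
#'
#' @param spikes An `fm_spikes`.
#' @param protocol An `fm_protocol`.
#' @param scene_categories Named character vector mapping `scene_id` to a
#'   category label (e.g. face, hand, body, object).
#' @param window_evoked,window_baseline Response windows, ms after onset.
#' @param t_max PSTH extent in ms.
#' @return List with `means` (channels x categories matrix, Hz) and `psth`
#'   (named list of population mean traces, Hz, 1 ms bins).
#' @export
category_tuning <- function(spikes, protocol, scene_categories,
                            window_evoked = c(80, 250),
                            window_baseline = c(0, 30), t_max = 400) {
  ev <- protocol$events
  cats <- sort(unique(scene_categories))
  ev_cat <- scene_categories[ev$scene_id]
  nch <- spikes$n_channels
  means <- matrix(NA_real_, nch, length(cats),
                  dimnames = list(NULL, cats))
  psth <- setNames(vector("list", length(cats)), cats)
  for (cat in cats) {
    idx <- which(ev_cat == cat)
    tot <- numeric(t_max)
    for (ch in seq_len(nch)) {
      st <- spikes$channels[[ch]]
      e <- window_counts(st, ev$onset_ms[idx], window_evoked) /
        diff(window_evoked) * 1000
      b <- window_counts(st, ev$onset_ms[idx], window_baseline) /
        diff(window_baseline) * 1000
      means[ch, cat] <- mean(e - b)
      tot <- tot + colSums(aligned_counts(st, ev$onset_ms[idx], t_max))
    }
    psth[[cat]] <- tot / (length(idx) * nch) * 1000
  }
  list(means = means, psth = psth, categories = cats)
}

#' Mean per-channel selectivity index between two categories
#'
#' Computes the index per channel and averages; channels with a negative
#' response to either category are excluded (the index is only bounded for
#' nonnegative responses), and the number excluded is reported.
#'
#' @param tuning Output of [category_tuning()].
#' @param cat1,cat2 Category names.
#' @return List with `mean_index`, `sd_index`, `per_channel`, `n_excluded`.
#' @export
category_selectivity <- function(tuning, cat1, cat2) {
  r1 <- tuning$means[, cat1]; r2 <- tuning$means[, cat2]
  keep <- r1 >= 0 & r2 >= 0 & (r1 + r2) > 0
  idx <- (r1[keep] - r2[keep]) / (r1[keep] + r2[keep])
  list(mean_index = mean(idx), sd_index = stats::sd(idx),
       per_channel = idx, n_excluded = sum(!keep))
}

#' Visually responsive channels
#'
#' A channel counts as visually responsive when its evoked response exceeds
#' baseline at `z >= z_thresh` over all probe presentations (z computed from
#' the across-presentation spread of evoked-minus-baseline rates).
#'
#' @param spikes,protocol Probe session.
#' @param window_evoked,window_baseline Response windows.
#' @param z_thresh Threshold (default 2).
#' @return Integer vector of responsive channel indices.
#' @export
responsive_channels <- function(spikes, protocol, window_evoked = c(80, 250),
                                window_baseline = c(0, 30), z_thresh = 2) {
  ev <- protocol$events
  which(vapply(seq_len(spikes$n_channels), function(ch) {
    st <- spikes$channels[[ch]]
    e <- window_counts(st, ev$onset_ms, window_evoked) /
      diff(window_evoked) * 1000
    b <- window_counts(st, ev$onset_ms, window_baseline) /
      diff(window_baseline) * 1000
    d <- e - b
    se <- stats::sd(d) / sqrt(length(d))
    is.finite(se) && se > 0 && mean(d) / se >= z_thresh
  }, logical(1)))
}
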