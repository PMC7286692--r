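#' @title Region-conditioned PSTHs, bin-wise FDR statistics and latency
#' @name region_stats
NULL

#' Gaussian PSTH smoothing
#'
#' Gaussian kernel truncated to a `window_ms` support (default 20 ms, sigma =
#' window/4 = 5 ms), edge-normalised so that a constant trace is unchanged.
#'
#' @param x Numeric vector or matrix (rows smoothed independently).
#' @param sd_ms Kernel standard deviation (default 5).
#' @param window_ms Kernel support (default 20).
#' @return Smoothed object of the same shape.
#' @export
smooth_psth <- function(x, sd_ms = 5, window_ms = 20) {
  half <- floor(window_ms / 2)
  k <- stats::dnorm(-half:half, sd = sd_ms)
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    out <- out[(half + 1):(half + n)]
    norm <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                          sides = 2)[(half + 1):(half + n)]
    as.numeric(out / norm)
  }
  if (is.matrix(x)) t(apply(x, 1, sm1)) else sm1(x)
}

#' Select region objects from a scene by label and/or name
#'
#' Returns a selector function for [region_traces()] / [region_psth()].
#'
#' @param label Region label(s) to match (or `NULL` for any).
#' @param name Region name(s) to match (or `NULL` for any).
#' @return Function `scene -> list of regions`.
#' @export
region_selector <- function(label = NULL, name = NULL) {
  force(label); force(name)
  function(scene) scene_regions(scene, label = label, name = name)
}

# Logical index over protocol events: does the image coordinate over the RF
# centre (c = r - g) fall inside (or, with complement, outside) the selected
# regions of that event's scene?
events_in_region <- function(protocol, scenes, rf_center, selector,
                             complement = FALSE) {
  ev <- protocol$events
  cx <- rf_center[1] - ev$grid_x
  cy <- rf_center[2] - ev$grid_y
  inside <- logical(nrow(ev))
  for (sid in unique(ev$scene_id)) {
    idx <- which(ev$scene_id == sid)
    regs <- selector(scenes[[sid]])
    hit <- rep(FALSE, length(idx))
    for (reg in regs)
      hit <- hit | point_in_region(reg, cbind(cx[idx], cy[idx]))
    inside[idx] <- hit
  }
  if (complement) !inside else inside
}

#' Per-image region-conditioned firing-rate traces
#'
#' A presentation contributes to a region's trace iff the image coordinate
#' over the RF centre lies inside the region; contributions are averaged
#' over presentations (and channels) within each image.
#'
#' @param spikes An `fm_spikes`.
#' @param protocol An `fm_protocol`.
#' @param scenes Named scene list.
#' @param selector Region selector from [region_selector()] (or any function
#'   `scene -> list of regions`).
#' @param rf_center RF centre in degrees from fixation.
#' @param complement If `TRUE`, use presentations *outside* the selected
#'   regions (the non-region control).
#' @param t_max Trace length, ms.
#' @param channels Channel indices (default all).
#' @return Matrix images x time (Hz, 1 ms bins), rownames = scene ids;
#'   attribute `n_presentations` gives per-image presentation counts. Scenes
#'   with no contributing presentation are dropped; an error of class
#'   `facemap_empty_region` is raised if none remain.
#' @export
region_traces <- function(spikes, protocol, scenes, selector, rf_center,
                          complement = FALSE, t_max = 400, channels = NULL) {
  ev <- protocol$events
  sel <- events_in_region(protocol, scenes, rf_center, selector, complement)
  if (!any(sel))
    fm_error("facemap_empty_region",
             "no presentation falls inside the selected region(s)")
  if (is.null(channels)) channels <- seq_len(spikes$n_channels)
  ids <- unique(ev$scene_id)
  rows <- list(); npres <- integer(0)
  for (sid in ids) {
    idx <- which(sel & ev$scene_id == sid)
    if (length(idx) == 0) next
    tot <- numeric(t_max)
    for (ch in channels)
      tot <- tot + colSums(aligned_counts(spikes$channels[[ch]],
                                          ev$onset_ms[idx], t_max))
    rows[[sid]] <- tot / (length(idx) * length(channels)) * 1000
    npres[sid] <- length(idx)
  }
  if (length(rows) == 0)
    fm_error("facemap_empty_region", "no image contributes to the region")
  out <- do.call(rbind, rows)
  attr(out, "n_presentations") <- npres
  out
}

#' Region-conditioned population PSTH with confidence band
#'
#' Per-image traces from [region_traces()], Gaussian-smoothed last, with the
#' across-image mean and 95% confidence band (t-based, across images — the
#' same unit as the paired tests).
#'
#' @inheritParams region_traces
#' @param smooth_sd_ms,smooth_window_ms Smoothing kernel (default 5 / 20 ms).
#' @return Object of class `"fm_psth"`: `time_ms`, `per_image` (smoothed
#'   traces), `mean`, `ci_lo`, `ci_hi`, `n_images`.
#' @export
region_psth <- function(spikes, protocol, scenes, selector, rf_center,
                        complement = FALSE, t_max = 400, channels = NULL,
                        smooth_sd_ms = 5, smooth_window_ms = 20) {
  tr <- region_traces(spikes, protocol, scenes, selector, rf_center,
                      complement = complement, t_max = t_max,
                      channels = channels)
  sm <- smooth_psth(tr, sd_ms = smooth_sd_ms, window_ms = smooth_window_ms)
  rownames(sm) <- rownames(tr)
  n <- nrow(sm)
  mu <- colMeans(sm)
  if (n > 1) {
    se <- apply(sm, 2, stats::sd) / sqrt(n)
    tq <- stats::qt(0.975, n - 1)
  } else {
    se <- rep(0, ncol(sm)); tq <- 0
  }
  structure(list(time_ms = seq_len(ncol(sm)) - 0.5, per_image = sm,
                 mean = mu, ci_lo = mu - tq * se, ci_hi = mu + tq * se,
                 n_images = n,
                 smoothing = c(sd_ms = smooth_sd_ms,
                               window_ms = smooth_window_ms)),
            class = "fm_psth")
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q` (via adjusted p-values).
#'
#' @param pvals Vector of p-values.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(q > 0, q < 1)
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Bin-wise paired t-tests with FDR correction and latency extraction
#'
#' For each 1 ms bin, a two-sided paired t-test across images between the
#' target and control traces; p-values are BH-FDR corrected at level `q`;
#' maximal runs of rejected bins are reported and the latency is the start
#' of the first run of at least `min_run_ms` consecutive significant bins.
#'
#' @param traces_a,traces_b Matrices images x time on the same image set
#'   (rows paired; if both have rownames, rows are aligned by name).
#' @param q FDR level (default 0.05).
#' @param min_run_ms Minimum run length for a significant window / latency
#'   (default 5).
#' @return Object of class `"fm_sigtrace"`: `p`, `rejected`, `windows`
#'   (data.frame start/end/length in ms), `latency_ms` (NA when no window
#'   reaches `min_run_ms`), `t`, `n_images`.
#' @export
binwise_paired_tests <- function(traces_a, traces_b, q = 0.05,
                                 min_run_ms = 5) {
  if (!is.null(rownames(traces_a)) && !is.null(rownames(traces_b))) {
    common <- intersect(rownames(traces_a), rownames(traces_b))
    traces_a <- traces_a[common, , drop = FALSE]
    traces_b <- traces_b[common, , drop = FALSE]
  }
  n <- nrow(traces_a)
  if (n < 3 || nrow(traces_b) != n)
    fm_error("facemap_insufficient_pairs",
             "paired bin-wise tests require at least 3 matched images")
  d <- traces_a - traces_b
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  rej <- bh_fdr(p, q)
  r <- rle(rej)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  wins <- data.frame(start_ms = starts[r$values] - 1,
                     end_ms = ends[r$values],
                     length_ms = r$lengths[r$values])
  lat <- NA_real_
  ok <- wins$length_ms >= min_run_ms
  if (any(ok)) lat <- wins$start_ms[which(ok)[1]]
  structure(list(p = p, rejected = rej, windows = wins, latency_ms = lat,
                 t = tstat, n_images = n, q = q, min_run_ms = min_run_ms),
            class = "fm_sigtrace")
}

#' Half-maximum latency of a response difference trace
#'
#' The first time at which the across-image mean difference trace reaches
#' half of its peak. Unlike the onset of the first FDR-significant window —
#' which systematically lags more for weaker effects — the half-max crossing
#' is invariant to the response amplitude, so differences of half-max
#' latencies recover injected latency differences.
#'
#' @param traces_a,traces_b Matrices images x time (rows aligned by name
#'   when both are named).
#' @param t_min_ms Ignore bins before this time (default 30; excludes
#'   pre-response noise from the peak search).
#' @return Latency in ms (`NA` if the peak difference is not positive).
#' @export
half_max_latency <- function(traces_a, traces_b, t_min_ms = 30) {
  if (!is.null(rownames(traces_a)) && !is.null(rownames(traces_b))) {
    common <- intersect(rownames(traces_a), rownames(traces_b))
    traces_a <- traces_a[common, , drop = FALSE]
    traces_b <- traces_b[common, , drop = FALSE]
  }
  d <- colMeans(traces_a) - colMeans(traces_b)
  tt <- seq_along(d) - 1
  d[tt < t_min_ms] <- 0
  pk <- max(d)
  if (pk <= 0) return(NA_real_)
  tt[which(d >= pk / 2)[1]]
}

#' Paired Wilcoxon signed-rank check
#'
#' Nonparametric verification of a paired contrast: the exact signed-rank
#' distribution for n <= 25 (computed by dynamic programming over the
#' rank-sum distribution, valid under ties), normal approximation above.
#' All-zero differences are degenerate and return p = 1 with a flag.
#'
#' @param values_a,values_b Paired observations (e.g. per-image window
#'   means).
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return List with `p`, `n_used` (nonzero differences), `degenerate`.
#' @export
wilcoxon_check <- function(values_a, values_b, exact_max = 25) {
  d <- values_a - values_b
  nz <- d != 0
  if (!any(nz)) return(list(p = 1, n_used = 0L, degenerate = TRUE))
  dd <- d[nz]
  n <- length(dd)
  if (n <= exact_max) {
    # doubled ranks are integers even under midrank ties
    r2 <- as.integer(round(2 * rank(abs(dd))))
    w_obs <- sum(r2[dd > 0])
    # distribution of the positive-rank sum over all 2^n sign assignments
    dist <- numeric(sum(r2) + 1)   # dist[w + 1] = #assignments with sum w
    dist[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w_axis <- seq_along(dist) - 1
    p <- min(1, 2 * min(sum(dist[w_axis >= w_obs]),
                        sum(dist[w_axis <= w_obs])))
  } else {
    res <- suppressWarnings(stats::wilcox.test(dd, mu = 0, exact = FALSE,
                                               correct = TRUE))
    p <- res$p.value
  }
  list(p = p, n_used = n, degenerate = FALSE)
}

#' Per-image, per-channel response differences between two map regions
#'
#' For each image and channel, the mean map value over nodes whose image
#' coordinate lies in region A minus the mean over region B, plus the
#' across-channel mean per image (the histogram data accompanying each
#' contrast figure).
#'
#' @param maps Nested list: `maps[[image]][[channel]]`, each an `fm_map` on
#'   the image-coordinate grid.
#' @param scenes Named scene list.
#' @param selector_a,selector_b Region selectors (see [region_selector()]).
#' @param complement_b If `TRUE`, region B is the complement of
#'   `selector_b`'s regions.
#' @return List with `per_channel` (data.frame image, channel, difference)
#'   and `per_image` (across-channel means).
#' @export
channel_difference_histogram <- function(maps, scenes, selector_a, selector_b,
                                         complement_b = FALSE) {
  rows <- list()
  for (sid in names(maps)) {
    sc <- scenes[[sid]]
    m0 <- maps[[sid]][[1]]
    pts <- cbind(rep(m0$x, each = length(m0$y)),
                 rep(m0$y, times = length(m0$x)))
    in_a <- rep(FALSE, nrow(pts)); in_b <- rep(FALSE, nrow(pts))
    for (reg in selector_a(sc)) in_a <- in_a | point_in_region(reg, pts)
    for (reg in selector_b(sc)) in_b <- in_b | point_in_region(reg, pts)
    if (complement_b) in_b <- !in_b
    for (ch in seq_along(maps[[sid]])) {
      v <- as.vector(maps[[sid]][[ch]]$values)
      rows[[length(rows) + 1L]] <- data.frame(
        image = sid, channel = ch,
        difference = mean(v[in_a], na.rm = TRUE) -
          mean(v[in_b], na.rm = TRUE))
    }
  }
  per_channel <- do.call(rbind, rows)
  per_image <- tapply(per_channel$difference, per_channel$image, mean)
  list(per_channel = per_channel, per_image = per_image)
}

#' Per-image mean rates in a window for a region (for Wilcoxon checks)
#'
#' @inheritParams region_traces
#' @param window_ms Analysis window.
#' @return Named numeric vector of per-image window-mean rates (Hz).
#' @export
region_window_means <- function(spikes, protocol, scenes, selector, rf_center,
                                window_ms = c(100, 250), complement = FALSE,
                                channels = NULL) {
  tr <- region_traces(spikes, protocol, scenes, selector, rf_center,
                      complement = complement, t_max = window_ms[2],
                      channels = channels)
  rowMeans(tr[, (window_ms[1] + 1):window_ms[2], drop = FALSE])
}
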