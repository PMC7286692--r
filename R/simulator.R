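#' @title Parametric face-cell model and inhomogeneous-Poisson spike simulator
#'
#' @description
#' Each simulated channel is a face cell with a 2D Gaussian spatial receptive
#' field and a set of additive drives with distinct latencies: an eye drive
#' (earliest), an intact-face drive, and contextual drives anchored to the
#' point where a body implies a face ought to be (slower and weaker), plus a
#' still weaker end-of-body (feet) drive. Face-shaped noise patches and
#' outlines carry a partial intrinsic face drive (they retain face shape
#' cues). A ceiling rule suppresses the contextual drive whenever an intact
#' face occupies the implied-face location, so bodies facilitate responses
#' only when the presence of a face is ambiguous. Rates are turned into spike
#' times by an inhomogeneous Poisson process on a 1 ms lattice.
#'
#' @name simulator
NULL

#' Construct a face-cell model
#'
#' @param rf_center_deg Receptive-field centre `c(x, y)`, degrees from
#'   fixation.
#' @param rf_sigma_deg RF Gaussian width (1 sigma), degrees. Defaults give the
#'   1-3 degree activating regions typical of these recordings.
#' @param baseline_hz Baseline firing rate (spikes/s).
#' @param gains Named peak-rate increments (spikes/s) per drive type:
#'   `eyes`, `face`, `context_implied_face`, `context_feet`. The contextual
#'   gain defaults to 0.4 of the face gain (a free model parameter).
#' @param latencies_ms Named response latencies per drive type. Defaults:
#'   eyes 70, face 95, context 130 (i.e. ~35 ms slower than intact faces).
#' @param kernel_rise_ms,kernel_decay_ms Alpha-like response kernel time
#'   constants (difference of exponentials, normalised to unit peak).
#' @param facelike_scale Fraction of the face gain carried by face-shaped
#'   noise patches and outlines (shape cues without face features).
#' @param inversion_attenuation Multiplier in `[0, 1]` applied to contextual
#'   gains in inverted configurations (ambiguous stimuli only).
#' @param ceiling_rule Logical; when `TRUE`, contextual drive is suppressed if
#'   an intact face covers the implied-face anchor.
#' @param area_latency_offset_ms Added to every latency (negative for PL,
#'   which precedes ML).
#' @return Object of class `"fm_cell"`.
#' @export
face_cell_model <- function(rf_center_deg = c(0.5, 0.5), rf_sigma_deg = 1,
                            baseline_hz = 5,
                            gains = c(eyes = 20, face = 40,
                                      context_implied_face = 16,
                                      context_feet = 6),
                            latencies_ms = c(eyes = 70, face = 95,
                                             context_implied_face = 130,
                                             context_feet = 130),
                            kernel_rise_ms = 10, kernel_decay_ms = 40,
                            facelike_scale = 0.3,
                            inversion_attenuation = 0.5,
                            ceiling_rule = TRUE,
                            area_latency_offset_ms = 0) {
  stopifnot(all(gains >= 0), all(latencies_ms >= 0), baseline_hz >= 0,
            rf_sigma_deg > 0, kernel_rise_ms > 0,
            kernel_decay_ms > kernel_rise_ms,
            inversion_attenuation >= 0, inversion_attenuation <= 1)
  structure(list(rf_center_deg = as.numeric(rf_center_deg),
                 rf_sigma_deg = rf_sigma_deg, baseline_hz = baseline_hz,
                 gains = gains, latencies_ms = latencies_ms,
                 kernel_rise_ms = kernel_rise_ms,
                 kernel_decay_ms = kernel_decay_ms,
                 facelike_scale = facelike_scale,
                 inversion_attenuation = inversion_attenuation,
                 ceiling_rule = ceiling_rule,
                 area_latency_offset_ms = area_latency_offset_ms),
            class = "fm_cell")
}

#' Construct an array of face cells with jittered RF centres
#'
#' @param n_channels Number of channels (>= 1).
#' @param center_deg Common RF centre around which channels jitter.
#' @param jitter_sd_deg SD of the per-channel RF-centre jitter (small relative
#'   to the RF width; channels within an array share receptive-field
#'   locations).
#' @param area_label `"ML"` or `"PL"`; PL latencies lead ML by
#'   `pl_lead_ms`.
#' @param pl_lead_ms Latency lead of PL over ML in ms.
#' @param seed Seed for the jitter.
#' @param ... Passed to [face_cell_model()].
#' @return Object of class `"fm_array"`: list of cells plus metadata.
#' @export
array_model <- function(n_channels = 8, center_deg = c(0.5, 0.5),
                        jitter_sd_deg = 0.15, area_label = c("ML", "PL"),
                        pl_lead_ms = 15, seed = 1, ...) {
  stopifnot(n_channels >= 1)
  area_label <- match.arg(area_label)
  set.seed(seed)
  offset <- if (area_label == "PL") -pl_lead_ms else 0
  cells <- lapply(seq_len(n_channels), function(i) {
    jit <- stats::rnorm(2, 0, jitter_sd_deg)
    face_cell_model(rf_center_deg = center_deg + jit,
                    area_latency_offset_ms = offset, ...)
  })
  structure(list(cells = cells, center_deg = center_deg,
                 area_label = area_label), class = "fm_array")
}

# Unit-peak stimulus-response kernel sampled at 1 ms: an attack-sustain-
# release envelope — exponential rise (tau = `rise`) to a plateau sustained
# for the stimulus ON duration, exponential release (tau = `decay`) after
# offset. Smooth, unimodal, half-max reached within ~rise*ln(2) ms of onset.
response_kernel <- function(rise, decay, on_ms = 100, tol = 1e-3) {
  tmax <- ceiling(on_ms + decay * log(1 / tol)) + 1
  t <- seq(0, tmax)
  k <- ifelse(t < on_ms, 1 - exp(-t / rise),
              (1 - exp(-on_ms / rise)) * exp(-(t - on_ms) / decay))
  k / max(k)
}

kernel_value <- function(cell, t, on_ms = 100) {
  kv <- response_kernel(cell$kernel_rise_ms, cell$kernel_decay_ms, on_ms)
  idx <- floor(t) + 1L
  out <- numeric(length(t))
  ok <- t >= 0 & idx <= length(kv)
  out[ok] <- kv[idx[ok]]
  out
}

# Enumerate a scene's drives: anchor point (image coordinates), drive type,
# gain scale, and whether the contextual inversion attenuation applies.
# The ceiling rule is resolved here: a body's implied-face drive is dropped
# when an intact face region covers the anchor.
scene_drive_table <- function(scene, ceiling_rule = TRUE,
                              facelike_scale = 0.3,
                              inversion_attenuation = 0.5) {
  faces <- scene_regions(scene, label = "face")
  rows <- list()
  push <- function(type, anchor, scale, inv_face = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, ax = anchor[1], ay = anchor[2], scale = scale,
      inv_face = inv_face)
  for (reg in scene$regions) {
    if (reg$label == "face")
      push("face", reg$center, 1, inv_face = scene$inverted)
    else if (reg$label == "eyes")
      push("eyes", reg$center, 1)
    else if (reg$label %in% c("noise_patch", "outline"))
      push("face", reg$center, facelike_scale)
    else if (reg$label == "body") {
      covered <- length(faces) > 0 &&
        any(vapply(faces, function(f) point_in_region(f, reg$implied_face),
                   logical(1)))
      if (!(ceiling_rule && covered)) {
        scale <- if (scene$inverted) inversion_attenuation else 1
        push("context_implied_face", reg$implied_face, scale)
        if (!is.null(reg$implied_feet))
          push("context_feet", reg$implied_feet, scale)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(type = character(), ax = numeric(), ay = numeric(),
                      scale = numeric(), inv_face = logical()))
  do.call(rbind, rows)
}

drive_gain_map <- function(cell) {
  c(eyes = unname(cell$gains["eyes"]), face = unname(cell$gains["face"]),
    context_implied_face = unname(cell$gains["context_implied_face"]),
    context_feet = unname(cell$gains["context_feet"]))
}

drive_latency_map <- function(cell) {
  c(eyes = unname(cell$latencies_ms["eyes"]),
    face = unname(cell$latencies_ms["face"]),
    context_implied_face = unname(cell$latencies_ms["context_implied_face"]),
    context_feet = unname(cell$latencies_ms["context_feet"])) +
    cell$area_latency_offset_ms
}

# Transient attenuation applied to inverted intact faces: the upright/inverted
# difference for real faces is confined to the kernel-rise period.
inverted_face_factor <- function(cell, t_since_latency) {
  1 - 0.3 * exp(-pmax(t_since_latency, 0) / cell$kernel_rise_ms)
}

#' Instantaneous firing rate of a cell for a scene at a grid position
#'
#' The deterministic rate model behind the simulator:
#' `rate(t) = baseline + sum_d gain_d * scale_d *`
#' `exp(-||anchor_d + g - rf||^2 / (2 sigma^2)) * kernel(t - latency_d)`.
#' Contextual drives are anchored to each body's implied-face point and are
#' suppressed by the ceiling rule when an intact face covers that point.
#'
#' @param cell An `fm_cell`.
#' @param scene An `fm_scene`.
#' @param grid_pos Image-centre offset from fixation, `c(x, y)` degrees.
#' @param t_since_onset Time(s) since stimulus onset, ms (vectorised).
#' @param on_ms Stimulus ON duration shaping the sustained kernel (default
#'   100).
#' @return Rate(s) in spikes/s, never negative.
#' @export
drive_rate <- function(cell, scene, grid_pos, t_since_onset, on_ms = 100) {
  stopifnot(all(t_since_onset >= 0))
  drives <- scene_drive_table(scene, ceiling_rule = cell$ceiling_rule,
                              facelike_scale = cell$facelike_scale,
                              inversion_attenuation = cell$inversion_attenuation)
  gains <- drive_gain_map(cell)
  lats <- drive_latency_map(cell)
  rate <- rep(cell$baseline_hz, length(t_since_onset))
  if (nrow(drives) == 0) return(rate)
  for (i in seq_len(nrow(drives))) {
    d2 <- (drives$ax[i] + grid_pos[1] - cell$rf_center_deg[1])^2 +
      (drives$ay[i] + grid_pos[2] - cell$rf_center_deg[2])^2
    w <- gains[[drives$type[i]]] * drives$scale[i] *
      exp(-d2 / (2 * cell$rf_sigma_deg^2))
    if (w == 0) next
    ts <- t_since_onset - lats[[drives$type[i]]]
    kv <- kernel_value(cell, ts, on_ms)
    if (drives$inv_face[i]) kv <- kv * inverted_face_factor(cell, ts)
    rate <- rate + w * kv
  }
  pmax(rate, 0)
}

#' Simulate a recording session as inhomogeneous-Poisson spike trains
#'
#' Rates from [drive_rate()] are superposed additively over concurrent
#' presentations above a single shared baseline, discretised on a 1 ms
#' lattice, and spikes are drawn per bin as Poisson counts (spike times at
#' bin centres). Drives whose spatial weight falls below `rate_floor_hz` are
#' skipped (the Gaussian overlap of a drive 10 degrees from the RF is
#' numerically negligible).
#'
#' @param array An `fm_array`.
#' @param protocol An `fm_protocol`.
#' @param scenes Named list of scenes covering every `scene_id` in the
#'   protocol.
#' @param seed Integer seed; identical seeds give identical spike times.
#' @param rate_floor_hz Threshold below which a presentation/drive weight is
#'   ignored.
#' @return Object of class `"fm_spikes"`: per-channel sorted spike times (ms)
#'   plus session metadata.
#' @export
simulate_session <- function(array, protocol, scenes, seed = 1,
                             rate_floor_hz = 0.05) {
  ev <- protocol$events
  missing <- setdiff(unique(ev$scene_id), names(scenes))
  if (length(missing) > 0)
    fm_error("facemap_unknown_scene",
             paste("protocol references unknown scenes:",
                   paste(missing, collapse = ", ")))
  duration <- protocol$duration_ms
  combo_key <- paste(ev$scene_id, ev$grid_x, ev$grid_y, sep = "|")
  u <- !duplicated(combo_key)
  U <- data.frame(scene_id = ev$scene_id[u], gx = ev$grid_x[u],
                  gy = ev$grid_y[u], key = combo_key[u],
                  stringsAsFactors = FALSE)
  ev_by_combo <- split(ev$onset_ms, factor(combo_key, levels = U$key))

  set.seed(seed)
  channels <- vector("list", length(array$cells))
  for (ci in seq_along(array$cells)) {
    cell <- array$cells[[ci]]
    drives_by_scene <- lapply(scenes, scene_drive_table,
                              ceiling_rule = cell$ceiling_rule,
                              facelike_scale = cell$facelike_scale,
                              inversion_attenuation = cell$inversion_attenuation)
    # expand drives over unique (scene, position) combos
    dcount <- vapply(drives_by_scene[U$scene_id], nrow, integer(1))
    if (sum(dcount) > 0) {
      D <- do.call(rbind, drives_by_scene[U$scene_id])
      rep_idx <- rep(seq_len(nrow(U)), times = dcount)
      gains <- drive_gain_map(cell)
      lats <- drive_latency_map(cell)
      d2 <- (D$ax + U$gx[rep_idx] - cell$rf_center_deg[1])^2 +
        (D$ay + U$gy[rep_idx] - cell$rf_center_deg[2])^2
      w <- unname(gains[D$type]) * D$scale * exp(-d2 / (2 * cell$rf_sigma_deg^2))
      keep <- which(w >= rate_floor_hz)
    } else keep <- integer(0)

    rate <- rep(cell$baseline_hz, duration)
    if (length(keep) > 0) {
      kern <- response_kernel(cell$kernel_rise_ms, cell$kernel_decay_ms,
                              on_ms = protocol$on_ms)
      tk <- seq_along(kern) - 1
      kern_inv <- kern * inverted_face_factor(cell, tk)
      L <- length(kern)
      for (j in keep) {
        type <- D$type[j]
        k <- if (D$inv_face[j]) kern_inv else kern
        lat <- round(lats[[type]])
        onsets <- ev_by_combo[[rep_idx[j]]]
        for (o in onsets) {
          i0 <- o + lat + 1
          i1 <- min(i0 + L - 1, duration)
          if (i0 > duration) next
          rate[i0:i1] <- rate[i0:i1] + w[j] * k[seq_len(i1 - i0 + 1)]
        }
      }
    }
    counts <- stats::rpois(duration, rate * 1e-3)
    nz <- which(counts > 0L)
    channels[[ci]] <- rep(nz - 0.5, counts[nz])
  }
  structure(list(channels = channels, duration_ms = duration,
                 n_channels = length(channels)), class = "fm_spikes")
}

#' Simulate a receptive-field probe session
#'
#' Flashes a small (~2x2 degree) face probe over a position grid centred at
#' fixation, 100 ms ON / 200 ms OFF, `reps` repetitions per position —
#' the standard RF-mapping protocol.
#'
#' @param array An `fm_array`.
#' @param grid_shape,spacing_deg Probe grid geometry (default 9 x 9 at 1
#'   degree).
#' @param reps Repetitions per position.
#' @param seed Integer seed.
#' @param grid_center_deg Centre of the probe grid (default fixation).
#' @return List with elements `spikes`, `protocol`, `scenes`.
#' @export
simulate_probe_session <- function(array, grid_shape = 9, spacing_deg = 1,
                                   reps = 10, seed = 1,
                                   grid_center_deg = c(0, 0)) {
  probe <- scene_spec("probe",
                      list(region("face", c(0, 0), c(1, 1))),
                      image_set = "intact")
  scenes <- list(probe = probe)
  protocol <- make_protocol(grid_shape, spacing_deg, grid_center_deg, scenes,
                            reps, seed = seed)
  spikes <- simulate_session(array, protocol, scenes, seed = seed + 1L)
  list(spikes = spikes, protocol = protocol, scenes = scenes)
}

#' Write spike times as a long-format CSV (channel, t_ms)
#' @param spikes An `fm_spikes`.
#' @param path Output path.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- data.frame(
    channel = rep(seq_along(spikes$channels),
                  vapply(spikes$channels, length, integer(1))),
    t_ms = unlist(spikes$channels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Spike counts of one channel in [onset + w1, onset + w2) for each onset.
window_counts <- function(spike_times, onsets, window) {
  a <- findInterval(onsets + window[1] - 1e-9, spike_times)
  b <- findInterval(onsets + window[2] - 1e-9, spike_times)
  b - a
}

# Presentation-aligned 1 ms bin counts: matrix n_onsets x t_max, bin t covers
# [t-1, t) ms after onset.
aligned_counts <- function(spike_times, onsets, t_max) {
  M <- matrix(0L, length(onsets), t_max)
  a <- findInterval(onsets - 1e-9, spike_times)
  b <- findInterval(onsets + t_max - 1e-9, spike_times)
  for (i in seq_along(onsets)) {
    if (b[i] > a[i]) {
      bins <- floor(spike_times[(a[i] + 1):b[i]] - onsets[i]) + 1
      M[i, ] <- tabulate(bins, t_max)
    }
  }
  M
}
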