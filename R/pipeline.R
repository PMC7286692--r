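#' @title Seeded end-to-end analysis pipeline
#' @name pipeline
NULL

#' Build a run configuration
#'
#' A run is reproducible from (config, seed) alone. Two presentation
#' profiles mirror the two recording configurations: `monkey1` uses a
#' 17 x 17 grid at 1 degree spacing with a 100-250 ms analysis window;
#' `monkey2` a 9 x 9 grid at 2 degrees with 150-300 ms.
#'
#' @param seed Master seed; per-stage streams are derived from it.
#' @param profile `"monkey1"` or `"monkey2"`.
#' @param n_channels Channels in the simulated array.
#' @param reps Repetitions per (scene, position).
#' @param n_images Exemplars per archetype used in the run.
#' @param q FDR level.
#' @param smooth_sd_ms PSTH smoothing kernel SD.
#' @param min_run_ms Minimum significant run for latency extraction.
#' @param n_perm Label-shuffle permutations for the RSA stage.
#' @param allow_any_reps Permit `reps` outside the standard 5-10 range.
#' @return Object of class `"fm_config"` (a named list).
#' @export
run_config <- function(seed = 1, profile = c("monkey2", "monkey1"),
                       n_channels = 4, reps = 5, n_images = 4, q = 0.05,
                       smooth_sd_ms = 5, min_run_ms = 5, n_perm = 500,
                       allow_any_reps = FALSE) {
  profile <- match.arg(profile)
  prof <- if (profile == "monkey1")
    list(grid_shape = 17, spacing_deg = 1, window_ms = c(100, 250))
  else list(grid_shape = 9, spacing_deg = 2, window_ms = c(150, 300))
  structure(c(list(seed = as.integer(seed), profile = profile), prof,
              list(n_channels = n_channels, reps = reps, n_images = n_images,
                   q = q, smooth_sd_ms = smooth_sd_ms,
                   min_run_ms = min_run_ms, n_perm = n_perm,
                   allow_any_reps = allow_any_reps)),
            class = "fm_config")
}

#' Validate a run configuration
#'
#' @param config An `fm_config` (or plain list).
#' @return `TRUE` invisibly if valid; otherwise an error of class
#'   `facemap_invalid_config` itemising every problem.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  if (!isTRUE(config$allow_any_reps) &&
      (config$reps < 5 || config$reps > 10))
    probs <- c(probs, "reps must lie in [5, 10] (set allow_any_reps to override)")
  if (!is.numeric(config$q) || config$q <= 0 || config$q >= 1)
    probs <- c(probs, "q must lie in (0, 1)")
  if (!config$profile %in% c("monkey1", "monkey2"))
    probs <- c(probs, "profile must be 'monkey1' or 'monkey2'")
  if (config$n_channels < 1) probs <- c(probs, "n_channels must be >= 1")
  if (config$n_images < 1) probs <- c(probs, "n_images must be >= 1")
  if (config$n_perm < 1) probs <- c(probs, "n_perm must be >= 1")
  if (length(probs) > 0)
    fm_error("facemap_invalid_config",
             paste0("invalid configuration:\n  - ",
                    paste(probs, collapse = "\n  - ")))
  invisible(TRUE)
}

# One master seed spawns named per-stage streams (kept below 2^31).
stage_seed <- function(seed, stage) {
  offs <- c(scenes = 101L, probe = 202L, main = 303L, orient = 404L,
            rsa = 505L, protocol = 606L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483587L
}

#' Run the full analysis pipeline and write all stage outputs
#'
#' Stages: scene generation, RF-probe simulation and Gaussian fitting, main
#' scene session simulation, image-registered response maps, region PSTHs
#' with FDR-corrected contrasts, body-orientation composite maps, and an RSA
#' stage on synthetic category features. Every table is written as CSV, the
#' configuration and a manifest (paths, md5 checksums, seed, timings) as
#' JSON. Outputs of completed stages survive a later stage's failure.
#'
#' @param config An `fm_config`.
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, profile = config$profile,
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   stages = list(), files = list())
  t_all <- Sys.time()
  out <- function(name) file.path(out_dir, name)
  done <- function(stage, t0, files) {
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      files = files)
  }

  t0 <- Sys.time()
  jsonlite::write_json(unclass(config), out("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  scenes <- c(make_scene_set("intact", config$n_images,
                             seed = stage_seed(config$seed, "scenes")),
              make_scene_set("occluded", config$n_images,
                             seed = stage_seed(config$seed, "scenes") + 1L))
  write_scenes_json(scenes, out("scenes.json"))
  done("scenes", t0, c("config.json", "scenes.json"))

  # --- RF mapping stage -------------------------------------------------
  t0 <- Sys.time()
  arr <- array_model(n_channels = config$n_channels, center_deg = c(0.5, 0.5),
                     seed = stage_seed(config$seed, "probe"))
  probe <- simulate_probe_session(arr, grid_shape = 9, spacing_deg = 1,
                                  reps = config$reps,
                                  seed = stage_seed(config$seed, "probe"))
  grids <- lapply(seq_len(config$n_channels), function(ch)
    probe_response_grid(probe$spikes, probe$protocol, ch))
  fits <- lapply(grids, fit_rf_gaussian)
  rf_df <- do.call(rbind, lapply(seq_along(fits), function(i) data.frame(
    channel = i, x = fits[[i]]$centroid_deg[1], y = fits[[i]]$centroid_deg[2],
    sigma_x = fits[[i]]$sigma_deg[1], sigma_y = fits[[i]]$sigma_deg[2],
    amplitude_hz = fits[[i]]$amplitude_hz, offset_hz = fits[[i]]$offset_hz,
    goodness = fits[[i]]$goodness)))
  utils::write.csv(rf_df, out("rf_fits.csv"), row.names = FALSE)
  pop_rf <- population_rf(grids)
  pop_fit <- fit_rf_gaussian(pop_rf)
  rf_center <- pop_fit$centroid_deg
  done("map_rf", t0, "rf_fits.csv")

  # --- main session + response maps ------------------------------------
  t0 <- Sys.time()
  protocol <- make_protocol(config$grid_shape, config$spacing_deg, rf_center,
                            scenes, config$reps,
                            seed = stage_seed(config$seed, "protocol"))
  spikes <- simulate_session(arr, protocol, scenes,
                             seed = stage_seed(config$seed, "main"))
  map_rows <- list()
  for (sid in names(scenes)) {
    m <- build_scene_response_map(spikes, protocol, sid, rf_center,
                                  window_ms = config$window_ms)
    sm <- scale_map(interpolate_map(m, px_per_deg = 2))
    map_rows[[sid]] <- data.frame(
      scene_id = sid, x = rep(m$x, each = length(m$y)),
      y = rep(m$y, times = length(m$x)), rate_hz = as.vector(m$values))
  }
  utils::write.csv(do.call(rbind, map_rows), out("response_maps.csv"),
                   row.names = FALSE)
  done("map_scenes", t0, "response_maps.csv")

  # --- region statistics ------------------------------------------------
  t0 <- Sys.time()
  occl <- scenes[grep("^occluded", names(scenes))]
  occl_protocol_ids <- names(occl)
  tr_a <- region_traces(spikes, protocol, scenes,
                        region_selector(label = "occluder"), rf_center)
  tr_b <- region_traces(spikes, protocol, scenes,
                        region_selector(label = c("occluder", "body", "face",
                                                  "eyes", "object")),
                        rf_center, complement = TRUE)
  tr_a <- tr_a[intersect(rownames(tr_a), occl_protocol_ids), , drop = FALSE]
  tr_b <- tr_b[intersect(rownames(tr_b), occl_protocol_ids), , drop = FALSE]
  sm_a <- smooth_psth(tr_a, sd_ms = config$smooth_sd_ms)
  sm_b <- smooth_psth(tr_b, sd_ms = config$smooth_sd_ms)
  rownames(sm_a) <- rownames(tr_a); rownames(sm_b) <- rownames(tr_b)
  sig <- binwise_paired_tests(sm_a, sm_b, q = config$q,
                              min_run_ms = config$min_run_ms)
  psth_df <- rbind(
    data.frame(condition = "occluded_face", bin_ms = seq_len(ncol(sm_a)) - 1,
               rate_hz = colMeans(sm_a)),
    data.frame(condition = "non_face", bin_ms = seq_len(ncol(sm_b)) - 1,
               rate_hz = colMeans(sm_b)))
  utils::write.csv(psth_df, out("region_psth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(bin_ms = seq_along(sig$p) - 1, p = sig$p,
                              rejected = sig$rejected),
                   out("significance.csv"), row.names = FALSE)
  done("region_stats", t0, c("region_psth.csv", "significance.csv"))

  # --- orientation composite -------------------------------------------
  t0 <- Sys.time()
  oscenes <- make_scene_set("body_orientations", 1,
                            seed = stage_seed(config$seed, "orient"))
  oprotocol <- make_protocol(9, 2, rf_center, oscenes, config$reps,
                             seed = stage_seed(config$seed, "orient") + 1L)
  ospikes <- simulate_session(arr, oprotocol, oscenes,
                              seed = stage_seed(config$seed, "orient") + 2L)
  omaps <- lapply(names(oscenes), function(sid)
    build_scene_response_map(ospikes, oprotocol, sid, rf_center,
                             window_ms = config$window_ms))
  names(omaps) <- sub(".*_o", "", names(oscenes))
  se_hz <- map_sampling_se(omaps[[1]], config)
  comp <- composite_orientation_map(omaps, baseline_hz = 5, se_hz = se_hz)
  utils::write.csv(data.frame(
    x = rep(comp$x, each = length(comp$y)),
    y = rep(comp$y, times = length(comp$x)),
    orientation_deg = as.vector(comp$orientation),
    masked = as.vector(comp$masked)),
    out("orientation_composite.csv"), row.names = FALSE)
  done("orientation_map", t0, "orientation_composite.csv")

  # --- RSA --------------------------------------------------------------
  t0 <- Sys.time()
  feats <- make_category_features(n_per_cat = 6, n_units = 40, lambda = 1,
                                  seed = stage_seed(config$seed, "rsa"))
  S <- pair_similarity(zscore_features(feats$features), "spearman")
  perm <- label_permutation_test(S, feats$labels, n_perm = config$n_perm,
                                 seed = stage_seed(config$seed, "rsa") + 1L)
  utils::write.csv(perm$summary, out("rsa_summary.csv"), row.names = FALSE)
  done("rsa", t0, "rsa_summary.csv")

  files <- unlist(lapply(manifest$stages, `[[`, "files"), use.names = FALSE)
  manifest$files <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(out(f)))))
  manifest$total_seconds <- round(
    as.numeric(difftime(Sys.time(), t_all, units = "secs")), 3)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Standard error of a single map node value under Poisson spiking: rate /
# (window * reps * channels) variance, evaluated at baseline-ish rates.
map_sampling_se <- function(map, config) {
  win_s <- diff(config$window_ms) / 1000
  sqrt(max(mean(map$values, na.rm = TRUE), 1) /
         (win_s * config$reps * config$n_channels))
}
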