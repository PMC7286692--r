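#' @title Canned simulate-then-recover experiments
#'
#' @description
#' Each experiment wires the synthetic generator, the simulator and one
#' analysis stage into a seeded end-to-end recovery study: inject a known
#' effect, run the pipeline, and measure how well it is recovered. These
#' functions back both the analysis scripts and the reproduction script.
#'
#' @name experiments
NULL

sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483587)
}

#' Receptive-field parameter recovery study
#'
#' Simulates probe sessions (9 x 9 grid, 1 degree spacing) for cells with
#' known RF centre and width, fits the 2D Gaussian, and scores recovery:
#' centroid within `tol_centroid_deg` and sigma within `tol_sigma_rel` of
#' truth.
#'
#' @param n_runs Number of seeded runs (default 50).
#' @param reps Probe repetitions per position (default 10).
#' @param baseline_hz,gain_hz Cell baseline and face-drive gain.
#' @param tol_centroid_deg,tol_sigma_rel Success tolerances.
#' @param seed Master seed.
#' @return List with `runs` (per-run data.frame) and `success_rate`.
#' @export
experiment_rf_recovery <- function(n_runs = 50, reps = 10, baseline_hz = 5,
                                   gain_hz = 40, tol_centroid_deg = 0.25,
                                   tol_sigma_rel = 0.2, seed = 1) {
  runs <- lapply(seq_len(n_runs), function(i) {
    s <- sub_seed(seed, i)
    set.seed(s)
    center <- stats::runif(2, -1.5, 1.5)
    sigma <- stats::runif(1, 0.7, 1.3)
    arr <- array_model(n_channels = 1, center_deg = center,
                       jitter_sd_deg = 0, seed = s,
                       rf_sigma_deg = sigma, baseline_hz = baseline_hz,
                       gains = c(eyes = 0, face = gain_hz,
                                 context_implied_face = 0, context_feet = 0))
    sess <- simulate_probe_session(arr, grid_shape = 9, spacing_deg = 1,
                                   reps = reps, seed = s + 1L)
    grid <- probe_response_grid(sess$spikes, sess$protocol, 1)
    fit <- fit_rf_gaussian(grid)
    data.frame(
      run = i, true_x = center[1], true_y = center[2], true_sigma = sigma,
      fit_x = fit$centroid_deg[1], fit_y = fit$centroid_deg[2],
      fit_sigma = mean(fit$sigma_deg),
      centroid_err = sqrt(sum((fit$centroid_deg - center)^2)),
      sigma_rel_err = abs(mean(fit$sigma_deg) - sigma) / sigma)
  })
  runs <- do.call(rbind, runs)
  runs$success <- runs$centroid_err <= tol_centroid_deg &
    runs$sigma_rel_err <= tol_sigma_rel
  list(runs = runs, success_rate = mean(runs$success))
}

registration_test_coords <- function() {
  list(c(2, -4), c(-4, 2), c(6, 0), c(0, 6), c(-2, -2))
}

#' Map registration oracle study
#'
#' Narrow-RF ("delta-responder") cells and scenes each containing a single
#' face at a known off-centre image coordinate: the reconstructed response
#' map's argmax must land on that coordinate exactly (no mirror or sign
#' error), and the full map must correlate with the noise-free rate-model
#' oracle.
#'
#' @param reps Repetitions (default 20).
#' @param n_seeds Seeds for the map-vs-oracle correlation (default 10).
#' @param seed Master seed.
#' @return List: `argmax_exact` (logical per test coordinate),
#'   `pearson_r` (per seed), plus details.
#' @export
experiment_map_registration <- function(reps = 20, n_seeds = 10, seed = 1) {
  r <- c(0.5, -0.5)
  cell <- face_cell_model(rf_center_deg = r, rf_sigma_deg = 0.4,
                          baseline_hz = 5,
                          gains = c(eyes = 0, face = 40,
                                    context_implied_face = 0,
                                    context_feet = 0))
  arr <- structure(list(cells = list(cell), center_deg = r,
                        area_label = "ML"), class = "fm_array")
  coords <- registration_test_coords()
  scenes <- setNames(lapply(seq_along(coords), function(i)
    scene_spec(paste0("delta_", i),
               list(region("face", coords[[i]], c(1, 1))))),
    paste0("delta_", seq_along(coords)))
  protocol <- make_protocol(9, 2, r, scenes, reps,
                            seed = sub_seed(seed, 1))
  spikes <- simulate_session(arr, protocol, scenes,
                             seed = sub_seed(seed, 2))
  argmax_exact <- vapply(seq_along(coords), function(i) {
    m <- build_scene_response_map(spikes, protocol, paste0("delta_", i), r,
                                  channel = 1)
    peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
    isTRUE(all.equal(c(m$x[peak[2]], m$y[peak[1]]), coords[[i]],
                     tolerance = 1e-9))
  }, logical(1))
  # map-vs-oracle fidelity: realistically tuned cells, a structured scene,
  # and the population map (channels are combined to improve signal to
  # noise, as in the main analysis)
  fcell <- face_cell_model(rf_center_deg = r, rf_sigma_deg = 1,
                           gains = context_cell_gains())
  farr <- structure(list(cells = rep(list(fcell), 8), center_deg = r,
                         area_label = "ML"), class = "fm_array")
  fscenes <- make_scene_set("intact", 1, seed = sub_seed(seed, 3))
  fprotocol <- make_protocol(9, 2, r, fscenes, reps,
                             seed = sub_seed(seed, 4))
  oracle <- oracle_response_map(fcell, fscenes[[1]], fprotocol)
  pearson_r <- vapply(seq_len(n_seeds), function(k) {
    sp <- simulate_session(farr, fprotocol, fscenes,
                           seed = sub_seed(seed, 10 + k))
    m <- build_scene_response_map(sp, fprotocol, names(fscenes)[1], r,
                                  channel = "population")
    stats::cor(as.vector(m$values), as.vector(oracle$values))
  }, numeric(1))
  list(argmax_exact = argmax_exact, pearson_r = pearson_r,
       all_exact = all(argmax_exact), mean_r = mean(pearson_r))
}

context_cell_gains <- function(gain_face = 40, context_frac = 0.4) {
  c(eyes = 0, face = gain_face,
    context_implied_face = context_frac * gain_face, context_feet = 6)
}

#' Context-latency recovery study
#'
#' Injects a face latency of 95 ms and a contextual (implied-face) latency of
#' 130 ms, then measures the difference between the FDR-window onsets of the
#' intact-face-vs-control and occluded-face-vs-control region contrasts. Eye
#' drive is disabled here so the face-region onset measures the injected face
#' latency rather than the earlier eye latency. Latency differences are taken
#' between half-max crossings of the region-minus-control difference traces
#' (amplitude-invariant; see [half_max_latency()]); the FDR-window onsets are
#' reported alongside.
#'
#' @param n_images Exemplars per image set (default 10).
#' @param reps Repetitions (default 10).
#' @param n_channels Channels (default 8).
#' @param seed Master seed.
#' @return List with `latency_face_ms`, `latency_context_ms`, `shift_ms`
#'   (half-max based) and `fdr_onset_face_ms`, `fdr_onset_context_ms`.
#' @export
experiment_context_latency <- function(n_images = 10, reps = 10,
                                       n_channels = 8, seed = 1) {
  scenes <- c(make_scene_set("intact", n_images, seed = sub_seed(seed, 1)),
              make_scene_set("occluded", n_images, seed = sub_seed(seed, 2)))
  r <- c(0.5, 0.5)
  arr <- array_model(n_channels = n_channels, center_deg = r,
                     jitter_sd_deg = 0.15, seed = sub_seed(seed, 3),
                     gains = context_cell_gains(),
                     latencies_ms = c(eyes = 70, face = 95,
                                      context_implied_face = 130,
                                      context_feet = 130))
  protocol <- make_protocol(9, 2, r, scenes, reps, seed = sub_seed(seed, 4))
  spikes <- simulate_session(arr, protocol, scenes, seed = sub_seed(seed, 5))
  structured <- region_selector(label = c("face", "eyes", "body", "occluder",
                                          "object"))
  trace_pair <- function(target_label, set_prefix) {
    ids <- grep(set_prefix, names(scenes), value = TRUE)
    a <- region_traces(spikes, protocol, scenes,
                       region_selector(label = target_label), r)
    b <- region_traces(spikes, protocol, scenes, structured, r,
                       complement = TRUE)
    keep <- intersect(intersect(rownames(a), rownames(b)), ids)
    list(a = smooth_named(a[keep, , drop = FALSE]),
         b = smooth_named(b[keep, , drop = FALSE]))
  }
  face_tr <- trace_pair("face", "^intact")
  occl_tr <- trace_pair("occluder", "^occluded")
  sig_face <- binwise_paired_tests(face_tr$a, face_tr$b)
  sig_occl <- binwise_paired_tests(occl_tr$a, occl_tr$b)
  lat_face <- half_max_latency(face_tr$a, face_tr$b)
  lat_occl <- half_max_latency(occl_tr$a, occl_tr$b)
  list(latency_face_ms = lat_face, latency_context_ms = lat_occl,
       shift_ms = lat_occl - lat_face,
       fdr_onset_face_ms = sig_face$latency_ms,
       fdr_onset_context_ms = sig_occl$latency_ms)
}

smooth_named <- function(m, ...) {
  out <- smooth_psth(m, ...)
  rownames(out) <- rownames(m)
  out
}

#' Contrast reproduction study (occluded / object-swap / ceiling)
#'
#' Simulates seeded sessions at experiment scale (8 images, 9 x 9 grid at 2
#' degrees, 5 repetitions) and asks, per session, whether the bin-wise paired
#' contrast yields an FDR-significant window of at least `min_run_ms`:
#' `"occluded"` contrasts occluded-face regions against non-face image parts,
#' `"swap"` contrasts a non-face object above a body against the identical
#' object elsewhere in the image, and `"ceiling"` contrasts a face above a
#' body against the same face without the body (which the ceiling rule
#' predicts to be indistinguishable).
#'
#' @param contrast One of `"occluded"`, `"swap"`, `"ceiling"`.
#' @param n_sessions Number of seeded sessions (default 50).
#' @param n_images Image exemplars per session (default 8; 7 for ceiling,
#'   matching the variants set).
#' @param reps,n_channels Session scale (defaults 5 and 8).
#' @param min_run_ms Minimum significant run (default 5).
#' @param seed Master seed.
#' @return List with `significant` (logical per session) and
#'   `fraction_significant`.
#' @export
experiment_contrast <- function(contrast = c("occluded", "swap", "ceiling"),
                                n_sessions = 50, n_images = NULL, reps = 5,
                                n_channels = 8, min_run_ms = 5, seed = 1) {
  contrast <- match.arg(contrast)
  if (is.null(n_images)) n_images <- if (contrast == "ceiling") 7 else 8
  r <- c(0.5, 0.5)
  significant <- vapply(seq_len(n_sessions), function(si) {
    s <- sub_seed(seed, 1000 + si)
    scenes <- switch(contrast,
      occluded = make_scene_set("occluded", n_images, seed = s),
      swap = make_scene_set("face_swapped", n_images, seed = s),
      ceiling = {
        all <- make_scene_set("face_variants_x_body", n_images, seed = s)
        all[grep("_face_(body|nobody)$", names(all))]
      })
    arr <- array_model(n_channels = n_channels, center_deg = r,
                       jitter_sd_deg = 0.15, seed = s + 1L,
                       gains = context_cell_gains())
    protocol <- make_protocol(9, 2, r, scenes, reps, seed = s + 2L)
    spikes <- simulate_session(arr, protocol, scenes, seed = s + 3L)
    pair <- contrast_traces(contrast, spikes, protocol, scenes, r)
    sig <- binwise_paired_tests(pair$a, pair$b, min_run_ms = min_run_ms)
    !is.na(sig$latency_ms)
  }, logical(1))
  list(significant = significant, fraction_significant = mean(significant),
       contrast = contrast, n_sessions = n_sessions)
}

contrast_traces <- function(contrast, spikes, protocol, scenes, r) {
  structured <- region_selector(label = c("face", "eyes", "body", "occluder",
                                          "mask_cover", "object",
                                          "noise_patch", "outline"))
  if (contrast == "occluded") {
    a <- region_traces(spikes, protocol, scenes,
                       region_selector(label = "occluder"), r)
    b <- region_traces(spikes, protocol, scenes, structured, r,
                       complement = TRUE)
  } else if (contrast == "swap") {
    a <- region_traces(spikes, protocol, scenes,
                       region_selector(name = "object_atop_body"), r)
    b <- region_traces(spikes, protocol, scenes,
                       region_selector(name = "object_control"), r)
  } else {
    a <- region_traces(spikes, protocol, scenes,
                       region_selector(label = "face"), r)
    b <- a[grep("_nobody$", rownames(a)), , drop = FALSE]
    a <- a[grep("_body$", rownames(a)), , drop = FALSE]
    rownames(a) <- sub("_body$", "", rownames(a))
    rownames(b) <- sub("_nobody$", "", rownames(b))
  }
  common <- intersect(rownames(a), rownames(b))
  list(a = smooth_named(a[common, , drop = FALSE]),
       b = smooth_named(b[common, , drop = FALSE]))
}

#' Type-I calibration of the bin-wise FDR engine
#'
#' Simulates exchangeable target/control per-image traces (identical Poisson
#' rate, no drive difference) and reports the fraction of experiments in
#' which any bin is FDR-rejected. FDR controls the expected false-discovery
#' fraction per family at q; the run-level any-rejection rate is a looser
#' summary bounded here at 10%.
#'
#' @param n_runs Number of seeded experiments (default 200).
#' @param n_images,t_max,rate_hz,n_pres Trace geometry (defaults 8 images,
#'   300 ms, 5 Hz, 40 pooled presentations).
#' @param seed Master seed.
#' @return List with `any_rejection` (logical) and `fraction_any_rejection`.
#' @export
experiment_type1 <- function(n_runs = 200, n_images = 8, t_max = 300,
                             rate_hz = 5, n_pres = 40, seed = 1) {
  any_rej <- vapply(seq_len(n_runs), function(i) {
    set.seed(sub_seed(seed, 2000 + i))
    lam <- rate_hz * 1e-3 * n_pres
    a <- matrix(stats::rpois(n_images * t_max, lam) / n_pres * 1000,
                n_images, t_max)
    b <- matrix(stats::rpois(n_images * t_max, lam) / n_pres * 1000,
                n_images, t_max)
    sig <- binwise_paired_tests(smooth_psth(a), smooth_psth(b))
    any(sig$rejected)
  }, logical(1))
  list(any_rejection = any_rej, fraction_any_rejection = mean(any_rej))
}

#' Body-orientation composite recovery study
#'
#' Simulates a session with headless bodies (8 exemplars, centred in the
#' image as in isolated-body stimulus sets) at eight orientations, builds
#' per-orientation population maps averaged across exemplars, and the
#' composite best-orientation map, and scores agreement of the winning
#' orientation with the geometric oracle: the orientation whose implied-face
#' anchor is nearest each grid point. The cells carry pure implied-face
#' context tuning (feet gain 0): the geometric oracle is defined over
#' implied-face anchors, and the end-of-body drive would add legitimate
#' secondary peaks the oracle does not model.
#'
#' @param reps,n_channels,n_exemplars Session scale (defaults: 5
#'   repetitions, 28 channels — the size of a visually responsive array —
#'   and 8 body exemplars as in the orientation image set).
#' @param seed Master seed.
#' @return List with `agreement` (fraction over unmasked points),
#'   `n_unmasked`, and the composite.
#' @export
experiment_orientation_composite <- function(reps = 5, n_channels = 28,
                                             n_exemplars = 8, seed = 1) {
  r <- c(0.5, 0.5)
  scenes <- make_scene_set("body_orientations", n_exemplars,
                           seed = sub_seed(seed, 1))
  arr <- array_model(n_channels = n_channels, center_deg = r,
                     jitter_sd_deg = 0.1, seed = sub_seed(seed, 2),
                     gains = c(eyes = 0, face = 40,
                               context_implied_face = 16, context_feet = 0))
  protocol <- make_protocol(9, 2, r, scenes, reps, seed = sub_seed(seed, 3))
  spikes <- simulate_session(arr, protocol, scenes, seed = sub_seed(seed, 4))
  orients_all <- seq(0, 315, by = 45)
  maps <- lapply(orients_all, function(o) {
    ids <- grep(paste0("_o", o, "$"), names(scenes), value = TRUE)
    population_map(lapply(ids, function(sid)
      build_scene_response_map(spikes, protocol, sid, r)))
  })
  names(maps) <- orients_all
  win_s <- 0.15
  se_hz <- sqrt(5 / (win_s * reps * n_channels * n_exemplars))
  comp <- composite_orientation_map(maps, baseline_hz = 5, se_hz = se_hz)
  one_per_orient <- scenes[paste0("body_orientations_1_o", orients_all)]
  anchors <- t(vapply(one_per_orient, function(sc)
    scene_regions(sc, "body")[[1]]$implied_face, numeric(2)))
  orients <- as.numeric(sub(".*_o", "", rownames(anchors)))
  pts <- cbind(rep(comp$x, each = length(comp$y)),
               rep(comp$y, times = length(comp$x)))
  d2 <- outer(pts[, 1], anchors[, 1], "-")^2 +
    outer(pts[, 2], anchors[, 2], "-")^2
  oracle <- matrix(orients[apply(d2, 1, which.min)],
                   length(comp$y), length(comp$x))
  unmasked <- !comp$masked
  agreement <- mean(comp$orientation[unmasked] == oracle[unmasked])
  list(agreement = agreement, n_unmasked = sum(unmasked),
       composite = comp, oracle = oracle)
}

#' Label-shuffle null calibration study
#'
#' Draws fully exchangeable iid features, runs the label-shuffle permutation
#' test, and reports how often the observed face-vs-body similarity falls
#' inside the 2.5-97.5% null bounds (nominally 95%).
#'
#' @param n_runs Seeded runs (default 500).
#' @param n_perm Permutations per run (default 500).
#' @param n_per_cat,n_units Feature geometry (defaults 6 and 20).
#' @param seed Master seed.
#' @return List with `covered` (logical) and `coverage`.
#' @export
experiment_rsa_calibration <- function(n_runs = 500, n_perm = 500,
                                       n_per_cat = 6, n_units = 20,
                                       seed = 1) {
  cats <- c("face", "body", "animal", "house", "object", "tool")
  labels <- rep(cats, each = n_per_cat)
  covered <- vapply(seq_len(n_runs), function(i) {
    s <- sub_seed(seed, 3000 + i)
    set.seed(s)
    X <- matrix(stats::rnorm(length(labels) * n_units), length(labels),
                n_units)
    S <- pair_similarity(zscore_features(X), "spearman")
    pt <- label_permutation_test(S, labels, n_perm = n_perm, seed = s + 1L)
    row <- pt$summary[pt$summary$category == "body", ]
    row$observed >= row$lo && row$observed <= row$hi
  }, logical(1))
  list(covered = covered, coverage = mean(covered))
}

#' Face-body representational merging study
#'
#' Generates category features in which faces and bodies share a latent
#' component of weight lambda and tracks the observed face-body similarity
#' against the 97.5% label-shuffle bound as lambda grows.
#'
#' @param lambdas Latent weights to scan.
#' @param n_perm Permutations per point (default 500).
#' @param seed Master seed.
#' @return Data frame with `lambda`, `observed`, `hi`, `crosses`.
#' @export
experiment_face_body_merge <- function(lambdas = c(0, 0.5, 1, 1.5, 2),
                                       n_perm = 500, seed = 1) {
  rows <- lapply(lambdas, function(lam) {
    feats <- make_category_features(n_per_cat = 8, n_units = 60, lambda = lam,
                                    seed = sub_seed(seed, 1))
    S <- pair_similarity(zscore_features(feats$features), "spearman")
    pt <- label_permutation_test(S, feats$labels, n_perm = n_perm,
                                 seed = sub_seed(seed, 2))
    row <- pt$summary[pt$summary$category == "body", ]
    data.frame(lambda = lam, observed = row$observed, hi = row$hi,
               crosses = row$observed > row$hi)
  })
  do.call(rbind, rows)
}

#' Category-selectivity study
#'
#' Presents single-category images (face, hand, body, object) centred on the
#' activating region of a simulated face-cell array and computes the mean
#' per-channel face-vs-nonface selectivity index.
#'
#' @param n_channels,reps Scale (defaults 8 and 10).
#' @param seed Master seed.
#' @return List with the tuning object and `face_vs_nonface`,
#'   `face_vs_body` mean indices.
#' @export
experiment_category_selectivity <- function(n_channels = 8, reps = 10,
                                            seed = 1) {
  r <- c(0.5, 0.5)
  mk <- function(id, regs) scene_spec(id, regs)
  scenes <- list(
    face = mk("face", list(region("face", c(0, 0), c(2, 2)),
                           region("eyes", c(0, 0.7), c(1.1, 0.45)))),
    body = mk("body", list(region("body", c(0, 0), c(BODY_RX, BODY_RY),
                                  implied_face = c(0, BODY_RY + FACE_R)))),
    hand = mk("hand", list(region("object", c(0, 0), c(1.5, 1.5),
                                  name = "hand"))),
    object = mk("object", list(region("object", c(0, 0), c(2, 2)))))
  arr <- array_model(n_channels = n_channels, center_deg = r,
                     jitter_sd_deg = 0.15, seed = sub_seed(seed, 1))
  protocol <- make_protocol(1, 0, r, scenes, reps, seed = sub_seed(seed, 2))
  spikes <- simulate_session(arr, protocol, scenes, seed = sub_seed(seed, 3))
  cats <- c(face = "face", body = "body", hand = "hand", object = "object")
  tuning <- category_tuning(spikes, protocol, cats)
  nonface <- rowMeans(tuning$means[, c("body", "hand", "object"),
                                   drop = FALSE])
  keep <- tuning$means[, "face"] >= 0 & nonface >= 0 &
    (tuning$means[, "face"] + nonface) > 0
  fvnf <- mean((tuning$means[keep, "face"] - nonface[keep]) /
                 (tuning$means[keep, "face"] + nonface[keep]))
  fvb <- category_selectivity(tuning, "face", "body")$mean_index
  list(tuning = tuning, face_vs_nonface = fvnf, face_vs_body = fvb)
}

#' Pipeline determinism check
#'
#' Runs the full pipeline twice with one configuration and seed and compares
#' the md5 checksums of every tabular (CSV) output byte for byte.
#'
#' @param config An `fm_config` (default: a small standard run).
#' @param base_dir Directory for the two runs (default a tempdir).
#' @return List with `identical` (logical) and the per-file comparison.
#' @export
experiment_determinism <- function(config = run_config(seed = 11),
                                   base_dir = tempfile("fm_det")) {
  d1 <- file.path(base_dir, "run1"); d2 <- file.path(base_dir, "run2")
  run_pipeline(config, d1)
  run_pipeline(config, d2)
  files <- sort(grep("\\.csv$", list.files(d1), value = TRUE))
  cmp <- data.frame(
    file = files,
    md5_run1 = unname(tools::md5sum(file.path(d1, files))),
    md5_run2 = unname(tools::md5sum(file.path(d2, files))))
  cmp$same <- cmp$md5_run1 == cmp$md5_run2
  list(identical = all(cmp$same), files = cmp)
}
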