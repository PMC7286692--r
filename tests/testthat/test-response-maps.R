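test_that("map registration places delta responses at their true image coordinates", {
  r <- c(0.5, -0.5)
  cell <- face_cell_model(rf_center_deg = r, rf_sigma_deg = 0.4,
                          gains = c(eyes = 0, face = 40,
                                    context_implied_face = 0,
                                    context_feet = 0))
  arr <- structure(list(cells = list(cell), center_deg = r,
                        area_label = "ML"), class = "fm_array")
  coords <- list(c(2, -4), c(-4, 2))
  scenes <- setNames(lapply(seq_along(coords), function(i)
    face_only_scene(coords[[i]], paste0("d", i), r = 1)),
    paste0("d", 1:2))
  protocol <- make_protocol(9, 2, r, scenes, reps = 10, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 2)
  for (i in 1:2) {
    m <- build_scene_response_map(spikes, protocol, paste0("d", i), r,
                                  channel = 1)
    peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
    expect_equal(c(m$x[peak[2]], m$y[peak[1]]), coords[[i]])
  }
  expect_error(build_scene_response_map(spikes, protocol, "nope", r),
               class = "facemap_unknown_scene")
})

test_that("position-independent responders give flat maps", {
  r <- c(0.5, 0.5)
  arr <- tiny_array(gains = c(eyes = 0, face = 0, context_implied_face = 0,
                              context_feet = 0), baseline_hz = 30)
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(9, 2, r, scenes, reps = 10, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 3)
  m <- build_scene_response_map(spikes, protocol, "s", r, channel = 1)
  expect_lt(stats::sd(as.vector(m$values)) / mean(m$values), 0.25)
})

test_that("intact-scene maps peak inside the face region", {
  r <- c(0.5, 0.5)
  arr <- structure(list(cells = rep(list(face_cell_model(
    rf_center_deg = r, gains = c(eyes = 0, face = 40,
                                 context_implied_face = 16,
                                 context_feet = 6))), 6),
    center_deg = r, area_label = "ML"), class = "fm_array")
  scenes <- make_scene_set("intact", 1, seed = 11)
  protocol <- make_protocol(9, 2, r, scenes, reps = 10, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 4)
  m <- build_scene_response_map(spikes, protocol, names(scenes)[1], r)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  face <- facemap:::scene_regions(scenes[[1]], "face")[[1]]
  expect_true(point_in_region(face, c(m$x[peak[2]], m$y[peak[1]])))
})

test_that("bilinear interpolation preserves nodes and matches the two-pass oracle", {
  set.seed(7)
  m <- structure(list(x = seq(-4, 4, by = 2), y = seq(-4, 4, by = 2),
                      values = matrix(stats::rnorm(25), 5, 5)),
                 class = "fm_map")
  d <- interpolate_map(m, px_per_deg = 2)
  # node values preserved bit-exactly
  for (i in seq_along(m$y)) for (j in seq_along(m$x))
    expect_identical(d$values[which(d$y == m$y[i]), which(d$x == m$x[j])],
                     m$values[i, j])
  # midpoint of 4 nodes equals their mean
  mid_i <- which(d$y == -1); mid_j <- which(d$x == 1)
  expect_equal(d$values[mid_i, mid_j],
               mean(m$values[2:3, 3:4]))
  # random interior points match the separable 1D x 1D oracle
  for (k in 1:20) {
    xt <- stats::runif(1, -4, 4); yt <- stats::runif(1, -4, 4)
    di <- which.min(abs(d$y - yt)); dj <- which.min(abs(d$x - xt))
    expect_equal(d$values[di, dj],
                 oracle_bilinear_point(m$x, m$y, m$values, d$x[dj], d$y[di]),
                 tolerance = 1e-12)
  }
  # no extrapolated extrema
  expect_gte(min(d$values), min(m$values))
  expect_lte(max(d$values), max(m$values))
})

test_that("percentile scaling clips, rescales monotonely, and survives constants", {
  set.seed(8)
  m <- structure(list(x = 1:20, y = 1:20,
                      values = matrix(stats::rnorm(400), 20, 20)),
                 class = "fm_map")
  s <- scale_map(m)
  qs <- stats::quantile(m$values, c(0.005, 0.995), names = FALSE)
  expect_equal(s$scaling_bounds, qs)
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_true(all(s$values[m$values <= qs[1]] == 0))
  expect_true(all(s$values[m$values >= qs[2]] == 1))
  # monotone: ordering of unclipped values preserved
  inside <- m$values > qs[1] & m$values < qs[2]
  expect_equal(order(m$values[inside]), order(s$values[inside]))
  flat <- m; flat$values[] <- 3
  expect_true(all(scale_map(flat)$values == 0.5))
})

test_that("temporal maps partition the analysis window", {
  r <- c(0.5, 0.5)
  arr <- tiny_array()
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(5, 2, r, scenes, reps = 5, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 5)
  tm <- temporal_maps(spikes, protocol, "s", r, channel = 1)
  expect_length(tm, 5)
  full <- build_scene_response_map(spikes, protocol, "s", r, channel = 1,
                                   window_ms = c(50, 250))
  binned <- Reduce(`+`, lapply(tm, `[[`, "values")) / 5
  expect_equal(binned, full$values, tolerance = 1e-9)
})

test_that("eye responses appear in earlier temporal bins than face responses", {
  r <- c(0.5, 0.5)
  cell <- face_cell_model(rf_center_deg = r,
                          gains = c(eyes = 30, face = 30,
                                    context_implied_face = 0,
                                    context_feet = 0),
                          latencies_ms = c(eyes = 60, face = 140,
                                           context_implied_face = 180,
                                           context_feet = 180))
  arr <- structure(list(cells = rep(list(cell), 4), center_deg = r,
                        area_label = "ML"), class = "fm_array")
  # eyes and face far apart so the 2-degree grid separates them
  # place regions on the even image-coordinate lattice realised by the grid
  sc <- scene_spec("ef", list(region("face", c(-4, -4), c(1.5, 1.5)),
                              region("eyes", c(2, 2), c(1, 0.5))))
  scenes <- list(ef = sc)
  protocol <- make_protocol(9, 2, r, scenes, reps = 10, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 6)
  tm <- temporal_maps(spikes, protocol, "ef", r)
  node_val <- function(map, p)
    map$values[which(map$y == p[2]), which(map$x == p[1])]
  # first bin reaching half of the node's own peak response
  first_half_max <- function(p) {
    v <- vapply(tm, node_val, numeric(1), p = p)
    which(v >= 5 + (max(v) - 5) / 2)[1]
  }
  expect_lt(first_half_max(c(2, 2)), first_half_max(c(-4, -4)))
})

test_that("population maps average channels pointwise", {
  mk <- function(v) structure(list(x = 1:3, y = 1:3,
                                   values = matrix(v, 3, 3)),
                              class = "fm_map")
  expect_equal(population_map(list(mk(2), mk(4)))$values, mk(3)$values)
  set.seed(9)
  ms <- lapply(1:3, function(i) mk(stats::rnorm(9)))
  manual <- (ms[[1]]$values + ms[[2]]$values + ms[[3]]$values) / 3
  expect_equal(population_map(ms)$values, manual)
  bad <- mk(1); bad$x <- 2:4
  expect_error(population_map(list(mk(1), bad)),
               class = "facemap_grid_mismatch")
})

test_that("composite orientation maps follow the exact baseline mask on constructed input", {
  mk <- function(v) structure(list(x = 1:3, y = 1:3,
                                   values = matrix(v, 3, 3)),
                              class = "fm_map")
  below <- setNames(lapply(c(0, 45, 90), function(o) mk(4)),
                    c(0, 45, 90))
  comp <- composite_orientation_map(below, baseline_hz = 5)
  expect_true(all(comp$masked))
  expect_true(all(is.na(comp$orientation)))
  winner <- below
  winner[["45"]]$values[] <- 6
  comp2 <- composite_orientation_map(winner, baseline_hz = 5)
  expect_true(all(!comp2$masked))
  expect_true(all(comp2$orientation == 45))
  bad <- winner
  bad[["90"]]$x <- 4:6
  expect_error(composite_orientation_map(bad, 5),
               class = "facemap_grid_mismatch")
})
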