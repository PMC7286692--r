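test_that("drive_rate reproduces the configured gains at the kernel peak", {
  cell <- face_cell_model(rf_center_deg = c(0, 0))
  sc <- face_only_scene(at = c(0, 0))
  t_peak <- cell$latencies_ms[["face"]] + 99  # end of the sustained plateau
  expect_equal(drive_rate(cell, sc, c(0, 0), t_peak),
               cell$baseline_hz + cell$gains[["face"]], tolerance = 1e-4)
  # before the latency the rate is exactly baseline
  expect_equal(drive_rate(cell, sc, c(0, 0), 90), cell$baseline_hz)
})

test_that("far-away implied faces leave the rate at baseline", {
  cell <- face_cell_model(rf_center_deg = c(0, 0))
  sc <- scene_spec("hb", list(region("body", c(10 - 4.5, -7) + c(0, 2.5),
                                     c(1.8, 3), implied_face = c(10, -2.5))))
  rates <- drive_rate(cell, sc, c(0, 0), seq(0, 400, by = 10))
  expect_equal(rates, rep(cell$baseline_hz, length(rates)), tolerance = 1e-6)
})

test_that("occluded-face context responds only after the context latency", {
  cell <- face_cell_model(rf_center_deg = c(0, 0),
                          gains = c(eyes = 0, face = 40,
                                    context_implied_face = 16,
                                    context_feet = 0))
  sc <- make_scene_set("occluded", 1, seed = 4)[[1]]
  anchor <- facemap:::scene_regions(sc, "body")[[1]]$implied_face
  g <- -anchor  # put the implied face over the RF centre
  lat <- cell$latencies_ms[["context_implied_face"]]
  expect_equal(drive_rate(cell, sc, g, lat - 5), cell$baseline_hz,
               tolerance = 1e-6)
  expect_gt(drive_rate(cell, sc, g, lat + 30), cell$baseline_hz + 10)
})

test_that("ceiling rule: a body under an intact face adds exactly nothing", {
  cell <- face_cell_model(rf_center_deg = c(0, 0))
  fc <- c(0, 1)
  face_alone <- scene_spec("fa", facemap:::person_regions(fc, with_body = FALSE))
  face_body <- scene_spec("fb", facemap:::person_regions(fc, with_body = TRUE))
  tt <- seq(0, 400, by = 7)
  for (g in list(c(0, -1), c(1, 0.5), c(0, -4.5))) {
    expect_identical(drive_rate(cell, face_alone, g, tt) -
                       drive_rate(cell, face_body, g, tt),
                     rep(0, length(tt)))
  }
  cell_nc <- face_cell_model(rf_center_deg = c(0, 0), ceiling_rule = FALSE)
  g <- -fc  # face over RF; its implied-face anchor now drives too
  expect_gt(max(drive_rate(cell_nc, face_body, g, tt) -
                  drive_rate(cell_nc, face_alone, g, tt)), 1)
})

test_that("rates are nonnegative across random scenes and times", {
  cell <- face_cell_model(rf_center_deg = c(0.5, 0.5))
  for (sc in make_scene_set("upright_inverted", 2, seed = 9)) {
    g <- stats::runif(2, -4, 4)
    expect_true(all(drive_rate(cell, sc, g, seq(0, 400, by = 13)) >= 0))
  }
})

test_that("baseline-only sessions produce Poisson counts at the right mean", {
  arr <- tiny_array(n = 2, gains = c(eyes = 0, face = 0,
                                     context_implied_face = 0,
                                     context_feet = 0), baseline_hz = 10)
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(5, 2, c(0, 0), scenes, reps = 5, seed = 1)
  protocol$duration_ms <- 100000  # pad the session to 100 s
  spikes <- simulate_session(arr, protocol, scenes, seed = 2)
  for (ch in 1:2) {
    n <- length(spikes$channels[[ch]])
    expect_lt(abs(n - 1000), 4 * sqrt(1000))
  }
})

test_that("simulation is seed-reproducible and distinct across seeds", {
  arr <- tiny_array()
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(3, 2, c(0.5, 0.5), scenes, reps = 5, seed = 1)
  s1 <- simulate_session(arr, protocol, scenes, seed = 42)
  s2 <- simulate_session(arr, protocol, scenes, seed = 42)
  s3 <- simulate_session(arr, protocol, scenes, seed = 43)
  expect_identical(s1$channels, s2$channels)
  expect_false(identical(s1$channels, s3$channels))
})

test_that("evoked counts scale linearly with gain", {
  scenes <- list(s = face_only_scene(at = c(0, 0), id = "s"))
  protocol <- make_protocol(1, 0, c(0, 0), scenes, reps = 200, seed = 1)
  counts_for <- function(gain, seed) {
    arr <- tiny_array(center = c(0, 0),
                      gains = c(eyes = 0, face = gain,
                                context_implied_face = 0, context_feet = 0))
    sp <- simulate_session(arr, protocol, scenes, seed = seed)
    ev <- protocol$events
    mean(facemap:::window_counts(sp$channels[[1]], ev$onset_ms, c(100, 250)) -
           facemap:::window_counts(sp$channels[[1]], ev$onset_ms, c(0, 30)) *
           (150 / 30))
  }
  e20 <- mean(vapply(1:3, function(s) counts_for(20, s), numeric(1)))
  e40 <- mean(vapply(1:3, function(s) counts_for(40, s), numeric(1)))
  expect_equal(e40 / e20, 2, tolerance = 0.15)
})

test_that("trial-averaged latency matches the configured latency within rise time", {
  scenes <- list(s = face_only_scene(at = c(0, 0), id = "s"))
  protocol <- make_protocol(1, 0, c(0, 0), scenes, reps = 400, seed = 1)
  arr <- tiny_array(center = c(0, 0),
                    gains = c(eyes = 0, face = 60, context_implied_face = 0,
                              context_feet = 0))
  sp <- simulate_session(arr, protocol, scenes, seed = 5)
  tr <- colMeans(facemap:::aligned_counts(sp$channels[[1]],
                                          protocol$events$onset_ms, 300)) * 1000
  tr <- smooth_psth(tr)
  half <- arr$cells[[1]]$baseline_hz + 30  # baseline + half the gain
  crossing <- which(tr >= half)[1] - 1
  expect_lt(abs(crossing - 95), arr$cells[[1]]$kernel_rise_ms)
})

test_that("PL leads ML in every drive latency", {
  pl <- array_model(2, area_label = "PL", seed = 1)
  ml <- array_model(2, area_label = "ML", seed = 1)
  expect_true(all(facemap:::drive_latency_map(pl$cells[[1]]) <
                    facemap:::drive_latency_map(ml$cells[[1]])))
})

test_that("unknown scenes in a protocol are rejected", {
  arr <- tiny_array()
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(3, 2, c(0, 0), scenes, reps = 5, seed = 1)
  expect_error(simulate_session(arr, protocol, list(), seed = 1),
               class = "facemap_unknown_scene")
})
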