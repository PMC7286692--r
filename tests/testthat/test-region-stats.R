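test_that("Gaussian smoothing leaves constant traces unchanged", {
  expect_equal(smooth_psth(rep(7, 100)), rep(7, 100))
  m <- matrix(3, 4, 50)
  expect_equal(smooth_psth(m), m)
})

whole_image_selector <- function(scene) {
  sq <- sqrt(2) * 8
  list(region("background_control", c(0, 0), c(sq, sq) / sqrt(2),
              shape = "polygon",
              vertices = rbind(c(-8, -8), c(8, -8), c(8, 8), c(-8, 8))))
}

test_that("a whole-image region reproduces the unconditioned PSTH", {
  r <- c(0.5, 0.5)
  arr <- tiny_array()
  scenes <- list(s = face_only_scene(id = "s"))
  protocol <- make_protocol(5, 2, r, scenes, reps = 5, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 2)
  tr <- region_traces(spikes, protocol, scenes, whole_image_selector, r,
                      t_max = 300)
  manual <- colMeans(facemap:::aligned_counts(
    spikes$channels[[1]], protocol$events$onset_ms, 300)) * 1000
  expect_equal(as.vector(tr["s", ]), manual)
})

test_that("disjoint undriven regions yield exchangeable traces and empty regions error", {
  r <- c(0.5, 0.5)
  arr <- tiny_array(gains = c(eyes = 0, face = 0, context_implied_face = 0,
                              context_feet = 0), baseline_hz = 25)
  sc <- scene_spec("ab", list(
    region("object", c(-3, -3), c(2, 2), name = "A"),
    region("object", c(3, 3), c(2, 2), name = "B")))
  scenes <- list(ab = sc)
  protocol <- make_protocol(9, 2, r, scenes, reps = 10, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 3)
  ta <- region_traces(spikes, protocol, scenes, region_selector(name = "A"), r)
  tb <- region_traces(spikes, protocol, scenes, region_selector(name = "B"), r)
  wa <- mean(ta[, 100:300]); wb <- mean(tb[, 100:300])
  se <- sqrt(25 / (0.2 * attr(ta, "n_presentations")[[1]])) *
    sqrt(2)
  expect_lt(abs(wa - wb), 4 * se)
  # a region no grid node ever lands in
  expect_error(
    region_traces(spikes, protocol, scenes,
                  region_selector(name = "nowhere"), r),
    class = "facemap_empty_region")
})

test_that("region PSTHs carry a confidence band containing the mean", {
  r <- c(0.5, 0.5)
  arr <- tiny_array()
  scenes <- make_scene_set("intact", 4, seed = 5)
  protocol <- make_protocol(9, 2, r, scenes, reps = 5, seed = 1)
  spikes <- simulate_session(arr, protocol, scenes, seed = 4)
  ps <- region_psth(spikes, protocol, scenes, region_selector(label = "face"),
                    r)
  expect_equal(ps$n_images, 4)
  expect_true(all(ps$ci_lo <= ps$mean + 1e-12))
  expect_true(all(ps$ci_hi >= ps$mean - 1e-12))
})

test_that("bin-wise paired tests reject nothing for identical traces", {
  set.seed(10)
  a <- matrix(stats::rpois(8 * 200, 4), 8, 200)
  sig <- binwise_paired_tests(a, a)
  expect_false(any(sig$rejected))
  expect_true(is.na(sig$latency_ms))
  expect_error(binwise_paired_tests(a[1:2, ], a[1:2, ]),
               class = "facemap_insufficient_pairs")
})

test_that("an injected offset interval is recovered with at most smoothing blur", {
  set.seed(11)
  base <- matrix(stats::rnorm(8 * 300, 10, 1), 8, 300)
  b <- base + matrix(stats::rnorm(8 * 300, 0, 1), 8, 300)
  a <- b
  a[, 121:200] <- a[, 121:200] + 8
  sig <- binwise_paired_tests(smooth_psth(a), smooth_psth(b))
  rej <- which(sig$rejected) - 1
  expect_true(all(rej >= 120 - 10 & rej <= 200 + 10))
  expect_true(all(seq(130, 190) %in% rej))
  expect_equal(sig$latency_ms, 120, tolerance = 11)
})

test_that("BH-FDR matches the brute-force step-up oracle", {
  expect_false(any(bh_fdr(rep(1, 20), 0.05)))
  expect_true(bh_fdr(0.04, 0.05))
  p <- c(rep(0.001, 50), rep(0.9, 150))
  sig_mask <- bh_fdr(p, 0.05)
  expect_identical(sig_mask, oracle_bh_step_up(p, 0.05))
  expect_equal(sum(sig_mask), 50)
  set.seed(12)
  for (i in 1:200) {
    p <- stats::runif(sample(5:200, 1))^sample(1:3, 1)
    q <- stats::runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q), oracle_bh_step_up(p, q))
  }
})

test_that("Wilcoxon check matches exact sign-assignment enumeration", {
  expect_equal(wilcoxon_check(rep(2, 6), rep(2, 6)),
               list(p = 1, n_used = 0L, degenerate = TRUE))
  # all 8 differences positive: p = 2 / 2^8
  res <- wilcoxon_check(11:18 + 0.5, 11:18 - 0.5)
  expect_equal(res$p, 2 / 256)
  set.seed(13)
  for (i in 1:10) {
    d <- stats::rnorm(10)
    res <- wilcoxon_check(d, rep(0, 10))
    expect_equal(res$p, oracle_wilcoxon_exact(d), tolerance = 1e-12)
  }
})

test_that("half-max latency finds injected onsets and their differences", {
  tr <- function(onset, amp, n = 6, t = 400) {
    k <- facemap:::response_kernel(10, 40, 100)
    v <- numeric(t)
    idx <- onset + seq_along(k)
    idx <- idx[idx <= t]
    v[idx] <- amp * k[seq_along(idx)]
    matrix(rep(v, n), n, t, byrow = TRUE)
  }
  zero <- matrix(0, 6, 400)
  l95 <- half_max_latency(tr(95, 30), zero)
  l130 <- half_max_latency(tr(130, 12), zero)
  expect_equal(l130 - l95, 35, tolerance = 2)
  expect_true(is.na(half_max_latency(zero, zero + 1)))
})

test_that("channel difference histograms recover constructed offsets", {
  sc <- scene_spec("s", list(region("object", c(-3, -3), c(2, 2), name = "A"),
                             region("object", c(3, 3), c(2, 2), name = "B")))
  mk <- function(bump) {
    v <- matrix(10, 9, 9)
    if (bump) v[3:4, 3:4] <- 12  # the four nodes inside region A at (-3, -3)
    structure(list(x = seq(-8, 8, 2), y = seq(-8, 8, 2), values = v),
              class = "fm_map")
  }
  maps <- list(s = list(mk(TRUE), mk(TRUE)))
  res <- channel_difference_histogram(maps, list(s = sc),
                                      region_selector(name = "A"),
                                      region_selector(name = "B"))
  expect_equal(res$per_channel$difference, c(2, 2))
  expect_equal(unname(res$per_image["s"]), 2)
  same <- channel_difference_histogram(maps, list(s = sc),
                                       region_selector(name = "A"),
                                       region_selector(name = "A"))
  expect_equal(same$per_channel$difference, c(0, 0))
})

test_that("simulated context delay appears in region PSTH latencies", {
  # small-scale smoke check: the occluded-face trace rises tens of ms after
  # the intact-face trace; the tight +/-5 ms recovery is asserted at full
  # experiment scale in the acceptance suite
  lat <- experiment_context_latency(n_images = 6, reps = 5, n_channels = 4,
                                    seed = 3)
  expect_gt(lat$shift_ms, 10)
  expect_lt(lat$shift_ms, 70)
})
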