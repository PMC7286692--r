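toy_images <- function(n = 6, side = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(stats::runif(side * side * 3),
                                       c(side, side, 3)))
}

test_that("pixel features vectorise images and identical images match", {
  imgs <- toy_images(4)
  imgs[[4]] <- imgs[[1]]
  f <- extract_features(imgs)
  expect_named(f, "pixel")
  expect_equal(dim(f$pixel), c(4, 8 * 8 * 3))
  expect_identical(f$pixel[1, ], f$pixel[4, ])
})

test_that("random projections preserve the rank geometry of separated clusters", {
  set.seed(2)
  centers <- matrix(stats::rnorm(3 * 50, sd = 6), 3, 50)
  X <- centers[rep(1:3, each = 5), ] + matrix(stats::rnorm(15 * 50), 15, 50)
  ex <- random_projection_extractor(input_dim = 50, n_units = 40, seed = 3)
  f <- extract_features(X, ex)
  d0 <- as.vector(stats::dist(X))
  d1 <- as.vector(stats::dist(f$proj1))
  expect_gt(stats::cor(d0, d1, method = "spearman"), 0.9)
})

test_that("z-scoring standardises units and drops constant ones", {
  set.seed(3)
  m <- matrix(stats::rnorm(30), 10, 3)
  z0 <- zscore_features(m)
  expect_equal(colMeans(z0), rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(z0, 2, stats::sd), rep(1, 3), ignore_attr = TRUE)
  expect_equal(zscore_features(z0)[, ], z0[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  m2 <- cbind(m, 5)
  z <- zscore_features(m2)
  expect_equal(ncol(z), 3)
  expect_equal(attr(z, "n_dropped"), 1)
  hand <- (m - matrix(colMeans(m), 10, 3, byrow = TRUE)) /
    matrix(apply(m, 2, stats::sd), 10, 3, byrow = TRUE)
  expect_equal(z0[, ], hand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pair similarities match definitions and the rank-correlation oracle", {
  set.seed(4)
  m <- matrix(stats::rnorm(20 * 15), 20, 15)
  m[2, ] <- m[1, ]
  S <- pair_similarity(m, "spearman")
  expect_equal(S[1, 2], 1)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 20))
  D <- pair_similarity(m, "negsqeuclid")
  expect_equal(D[1, 2], 0)
  anti <- rbind(c(1, -2), c(-1, 2))
  expect_equal(pair_similarity(anti, "pearson")[1, 2], -1)
  for (k in 1:15) {
    ij <- sample(20, 2)
    expect_equal(S[ij[1], ij[2]], oracle_spearman(m[ij[1], ], m[ij[2], ]),
                 tolerance = 1e-12)
  }
})

test_that("Spearman similarity is invariant under strictly monotone unit transforms", {
  set.seed(5)
  m <- matrix(stats::rnorm(8 * 10), 8, 10)
  warped <- exp(m) + m^3   # strictly increasing elementwise
  expect_equal(pair_similarity(m, "spearman"),
               pair_similarity(warped, "spearman"), ignore_attr = TRUE)
})

test_that("within/between summaries match brute-force pair enumeration", {
  labels <- rep(c("face", "body"), each = 3)
  S <- diag(6)
  S[1:3, 1:3] <- 1; S[4:6, 4:6] <- 1
  S[1:3, 4:6] <- 0; S[4:6, 1:3] <- 0
  W <- within_between_summary(S, labels)
  expect_equal(unname(W["face", "face"]), 1)
  expect_equal(unname(W["face", "body"]), 0)
  set.seed(6)
  S2 <- pair_similarity(matrix(stats::rnorm(6 * 9), 6, 9), "pearson")
  W2 <- within_between_summary(S2, labels)
  pairs <- combn(1:3, 2)
  expect_equal(unname(W2["face", "face"]),
               mean(S2[t(pairs)]))
  expect_equal(unname(W2["face", "body"]), mean(S2[1:3, 4:6]))
  # pooled mean over all pairs is invariant to relabelling
  perm <- sample(labels)
  pooled <- function(W, l) {
    n <- table(l)
    tot <- 0; cnt <- 0
    for (a in names(n)) for (b in names(n)) {
      k <- if (a == b) n[[a]] * (n[[a]] - 1) / 2 else 0.5 * n[[a]] * n[[b]]
      tot <- tot + W[a, b] * k; cnt <- cnt + k
    }
    tot / cnt
  }
  expect_equal(pooled(within_between_summary(S2, perm), perm),
               pooled(W2, labels), tolerance = 1e-12)
})

test_that("classical MDS recovers planar configurations up to rigid motion", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  emb <- mds_embedding(tri)
  d <- as.vector(stats::dist(emb))
  expect_equal(d, rep(d[1], 3), tolerance = 1e-9)
  set.seed(7)
  pts <- matrix(stats::rnorm(20), 10, 2)
  emb2 <- mds_embedding(pts)
  expect_lt(procrustes_error(pts, emb2), 1e-6)
  shifted <- pts + 5
  expect_equal(as.vector(stats::dist(mds_embedding(shifted))),
               as.vector(stats::dist(emb2)), tolerance = 1e-9)
})

test_that("label-shuffle nulls flag genuinely shared face/body structure", {
  feats <- make_category_features(n_per_cat = 8, n_units = 60, lambda = 2,
                                  seed = 8)
  S <- pair_similarity(zscore_features(feats$features), "spearman")
  pt <- label_permutation_test(S, feats$labels, n_perm = 300, seed = 9)
  row <- pt$summary[pt$summary$category == "body", ]
  expect_gt(row$observed, row$hi)
  expect_true(all(pt$summary$lo <= pt$summary$null_mean))
  expect_true(all(pt$summary$null_mean <= pt$summary$hi))
  expect_error(label_permutation_test(S, feats$labels, n_perm = 0),
               class = "facemap_invalid_permutations")
})

test_that("weight shuffling preserves layer weight multisets exactly", {
  net <- toy_relu_network(input_dim = 12, hidden_sizes = c(8, 4), seed = 10)
  set.seed(11)
  shuffled <- facemap:::shuffle_extractor_weights(net)
  for (ly in names(net$weights)) {
    expect_equal(dim(shuffled$weights[[ly]]), dim(net$weights[[ly]]))
    expect_equal(sort(shuffled$weights[[ly]]), sort(net$weights[[ly]]))
    expect_false(identical(shuffled$weights[[ly]], net$weights[[ly]]))
  }
})

test_that("weight-shuffle nulls separate structured toy networks and reject the pixel layer", {
  set.seed(12)
  feats <- make_category_features(n_per_cat = 6, n_units = 24, lambda = 2,
                                  seed = 12)
  # craft a first layer that amplifies the face/body shared component
  net <- toy_relu_network(input_dim = 24, hidden_sizes = c(10), seed = 13)
  sh <- feats$shared / sqrt(sum(feats$shared^2))
  net$weights$relu1 <- cbind(sh, -sh, net$weights$relu1[, -(1:2)] * 0.1)
  res <- weight_shuffle_test(net, feats$features, feats$labels,
                             n_perm = 60, seed = 14)
  row <- res$relu1$summary[res$relu1$summary$category == "body", ]
  expect_gt(row$observed, row$hi)
  res2 <- weight_shuffle_test(net, feats$features, feats$labels,
                              n_perm = 20, seed = 15)
  expect_equal(res$relu1$summary$observed, res2$relu1$summary$observed)
  expect_error(weight_shuffle_test(pixel_extractor(), feats$features,
                                   feats$labels),
               class = "facemap_unsupported_scheme")
})

test_that("face-body similarity grows with the shared latent weight", {
  m <- experiment_face_body_merge(lambdas = c(0, 1, 2), n_perm = 200, seed = 2)
  expect_true(all(diff(m$observed) > 0))
  expect_true(m$crosses[m$lambda == 2])
})
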