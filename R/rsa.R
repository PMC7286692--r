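#' @title Representational similarity analysis with permutation nulls
#'
#' @description
#' Category-labelled images (or precomputed feature vectors) are compared by
#' the pairwise similarity of their per-layer activation patterns; summaries
#' within and between categories are referenced against label-shuffle and
#' weight-shuffle permutation nulls, and visualised by classical MDS.
#' Feature extraction is a pluggable interface: the pixel layer is always
#' available, and random-projection layers or tiny seeded ReLU networks
#' stand in for large pretrained networks, whose trained weights are an
#' optional plug-in and are not required anywhere.
#'
#' @name rsa
NULL

#' Pixel feature extractor
#'
#' Exposes a single `"pixel"` layer: the vectorised colour-channel pixel
#' intensities of each image.
#' @return Object of class `"fm_extractor"`.
#' @export
pixel_extractor <- function() {
  structure(list(name = "pixel", layers = "pixel", weights = NULL,
                 fn = function(X, weights) list(pixel = X)),
            class = "fm_extractor")
}

#' Random-projection feature extractor
#'
#' A single linear layer of seeded Gaussian random projections (no training);
#' preserves pairwise geometry of well-separated clusters in expectation.
#'
#' @param input_dim Input (pixel) dimensionality.
#' @param n_units Number of projection units.
#' @param seed Seed for the projection matrix.
#' @export
random_projection_extractor <- function(input_dim, n_units = 64, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::rnorm(input_dim * n_units) / sqrt(input_dim),
              input_dim, n_units)
  structure(list(name = "random_projection", layers = "proj1",
                 weights = list(proj1 = W),
                 fn = function(X, weights) list(proj1 = X %*% weights$proj1)),
            class = "fm_extractor")
}

#' Tiny seeded ReLU network extractor
#'
#' A fully connected feed-forward network with rectified-linear layers and
#' seeded Gaussian weights; its per-layer weight matrices are accessible and
#' mutable, so it supports the weight-shuffle null.
#'
#' @param input_dim Input dimensionality.
#' @param hidden_sizes Integer vector of layer widths.
#' @param seed Seed for the weights.
#' @export
toy_relu_network <- function(input_dim, hidden_sizes = c(32, 16), seed = 1) {
  set.seed(seed)
  dims <- c(input_dim, hidden_sizes)
  weights <- list()
  for (l in seq_along(hidden_sizes))
    weights[[paste0("relu", l)]] <-
      matrix(stats::rnorm(dims[l] * dims[l + 1]) / sqrt(dims[l]),
             dims[l], dims[l + 1])
  structure(list(name = "toy_relu", layers = names(weights), weights = weights,
                 fn = function(X, weights) {
                   out <- list(); H <- X
                   for (nm in names(weights)) {
                     H <- pmax(H %*% weights[[nm]], 0)
                     out[[nm]] <- H
                   }
                   out
                 }),
            class = "fm_extractor")
}

images_to_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  do.call(rbind, lapply(images, function(im) as.numeric(im)))
}

#' Extract per-layer feature matrices for a set of images
#'
#' @param images List of image arrays (any shared shape) or an images x
#'   features matrix of precomputed vectors.
#' @param extractor An `fm_extractor` (default [pixel_extractor()]).
#' @return Named list of images x units matrices; a `"pixel"` layer is always
#'   included first.
#' @export
extract_features <- function(images, extractor = pixel_extractor()) {
  X <- images_to_matrix(images)
  feats <- tryCatch(extractor$fn(X, extractor$weights),
                    error = function(e)
                      fm_error("facemap_extractor_failure",
                               sprintf("extractor '%s' failed: %s",
                                       extractor$name, conditionMessage(e))))
  if (!"pixel" %in% names(feats)) feats <- c(list(pixel = X), feats)
  feats
}

#' Z-score features per unit across images
#'
#' Units (columns) are standardised to mean 0, SD 1 across images; zero-
#' variance units are undefined under correlation metrics and are dropped,
#' with the count recorded in attribute `n_dropped`.
#'
#' @param m Images x units matrix.
#' @return Standardised matrix.
#' @export
zscore_features <- function(m) {
  sds <- apply(m, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  out <- scale(m[, keep, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Pairwise image similarity matrix
#'
#' @param m Images x units feature matrix.
#' @param metric `"spearman"` (rank correlation across units, the default),
#'   `"pearson"`, or `"negsqeuclid"` (negative squared Euclidean distance).
#' @return Symmetric images x images matrix with attribute `metric`.
#' @export
pair_similarity <- function(m, metric = c("spearman", "pearson",
                                          "negsqeuclid")) {
  metric <- match.arg(metric)
  S <- switch(metric,
    spearman = stats::cor(t(m), method = "spearman"),
    pearson = stats::cor(t(m), method = "pearson"),
    negsqeuclid = -as.matrix(stats::dist(m))^2)
  attr(S, "metric") <- metric
  S
}

#' Within- and between-category mean similarities
#'
#' @param S Similarity matrix.
#' @param labels Category label per image.
#' @return Categories x categories matrix: diagonal = within-category means
#'   (self-pairs excluded), off-diagonal = between-category means.
#' @export
within_between_summary <- function(S, labels) {
  cats <- sort(unique(labels))
  out <- matrix(NA_real_, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (a in seq_along(cats)) for (b in seq_along(cats)) {
    ia <- which(labels == cats[a]); ib <- which(labels == cats[b])
    block <- S[ia, ib, drop = FALSE]
    if (a == b) {
      out[a, b] <- mean(block[upper.tri(block)])
    } else out[a, b] <- mean(block)
  }
  out
}

#' Classical MDS embedding of feature patterns
#'
#' Torgerson scaling of the squared Euclidean distances between (typically
#' z-scored) activation patterns; orientation and reflection of the embedding
#' are unconstrained.
#'
#' @param m Images x units feature matrix.
#' @param k Embedding dimension (default 2).
#' @return Images x k coordinate matrix.
#' @export
mds_embedding <- function(m, k = 2) {
  stats::cmdscale(stats::dist(m), k = k)
}

face_vs_category_means <- function(S, labels, face_label = "face") {
  fi <- which(labels == face_label)
  others <- setdiff(sort(unique(labels)), face_label)
  v <- colMeans(S[fi, , drop = FALSE])
  vapply(others, function(cat) mean(v[labels == cat]), numeric(1))
}

#' Label-shuffle permutation null for face-vs-category similarity
#'
#' Holds face labels fixed, shuffles the labels of non-face images, and
#' recomputes the mean face-vs-category similarities, yielding per-category
#' null distributions summarised by their mean and 2.5/97.5 percentiles.
#'
#' @param S Similarity matrix.
#' @param labels Category label per image.
#' @param n_perm Number of permutations (default 2500).
#' @param seed Integer seed.
#' @param face_label The held-fixed label (default `"face"`).
#' @return Object of class `"fm_perm_null"`: data.frame with one row per
#'   non-face category (`observed`, `null_mean`, `lo`, `hi`), plus `n_perm`
#'   and `scheme = "label_shuffle"`.
#' @export
label_permutation_test <- function(S, labels, n_perm = 2500, seed = 1,
                                   face_label = "face") {
  if (n_perm < 1)
    fm_error("facemap_invalid_permutations",
             "permutation test requires n_perm >= 1")
  set.seed(seed)
  fi <- which(labels == face_label)
  nf <- which(labels != face_label)
  others <- setdiff(sort(unique(labels)), face_label)
  v <- colMeans(S[fi, , drop = FALSE])   # mean similarity of each image to faces
  obs <- vapply(others, function(cat) mean(v[labels == cat]), numeric(1))
  nf_labels <- labels[nf]
  vnf <- v[nf]
  null <- matrix(NA_real_, n_perm, length(others),
                 dimnames = list(NULL, others))
  for (p in seq_len(n_perm)) {
    perm <- nf_labels[sample.int(length(nf_labels))]
    null[p, ] <- vapply(others, function(cat) mean(vnf[perm == cat]),
                        numeric(1))
  }
  structure(list(summary = data.frame(
    comparison = paste0(face_label, "_vs_", others),
    category = others, observed = unname(obs),
    null_mean = colMeans(null),
    lo = apply(null, 2, stats::quantile, 0.025, names = FALSE),
    hi = apply(null, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL),
    n_perm = n_perm, scheme = "label_shuffle"),
    class = "fm_perm_null")
}

shuffle_extractor_weights <- function(extractor) {
  extractor$weights <- lapply(extractor$weights, function(W) {
    matrix(W[sample.int(length(W))], nrow(W), ncol(W))
  })
  extractor
}

#' Weight-shuffle permutation null (untrained-network control)
#'
#' Per permutation, every layer's weights are randomly permuted in place —
#' preserving each layer's weight distribution exactly while destroying its
#' learned structure — features are re-extracted and face-vs-category mean
#' similarities recomputed.
#'
#' @param extractor An `fm_extractor` with accessible weights (the pixel
#'   extractor has none and is rejected).
#' @param images Image list or feature matrix (passed to
#'   [extract_features()]).
#' @param labels Category label per image.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @param metric Similarity metric.
#' @param face_label Held-out label.
#' @return Named list (one `fm_perm_null`-style element per layer) with
#'   `scheme = "weight_shuffle"`.
#' @export
weight_shuffle_test <- function(extractor, images, labels, n_perm = 500,
                                seed = 1, metric = "spearman",
                                face_label = "face") {
  if (is.null(extractor$weights))
    fm_error("facemap_unsupported_scheme",
             sprintf("extractor '%s' exposes no weights; weight shuffling unsupported",
                     extractor$name))
  if (n_perm < 1)
    fm_error("facemap_invalid_permutations",
             "permutation test requires n_perm >= 1")
  X <- images_to_matrix(images)
  others <- setdiff(sort(unique(labels)), face_label)
  layer_stats <- function(ex) {
    feats <- extract_features(X, ex)
    feats <- feats[setdiff(names(feats), "pixel")]
    lapply(feats, function(m)
      face_vs_category_means(pair_similarity(zscore_features(m), metric),
                             labels, face_label))
  }
  obs <- layer_stats(extractor)
  set.seed(seed)
  null <- lapply(obs, function(o)
    matrix(NA_real_, n_perm, length(others), dimnames = list(NULL, others)))
  for (p in seq_len(n_perm)) {
    st <- layer_stats(shuffle_extractor_weights(extractor))
    for (ly in names(st)) null[[ly]][p, ] <- st[[ly]]
  }
  out <- lapply(names(obs), function(ly) {
    structure(list(summary = data.frame(
      comparison = paste0(face_label, "_vs_", others),
      category = others, observed = unname(obs[[ly]]),
      null_mean = colMeans(null[[ly]]),
      lo = apply(null[[ly]], 2, stats::quantile, 0.025, names = FALSE),
      hi = apply(null[[ly]], 2, stats::quantile, 0.975, names = FALSE),
      row.names = NULL),
      n_perm = n_perm, scheme = "weight_shuffle", layer = ly),
      class = "fm_perm_null")
  })
  setNames(out, names(obs))
}

#' Synthetic category feature generator
#'
#' Gaussian feature vectors for six categories with a per-category mean
#' pattern; faces and bodies additionally share a latent component of weight
#' `lambda`, the knob that merges their representations.
#'
#' @param n_per_cat Images per category.
#' @param n_units Feature dimensionality.
#' @param lambda Weight of the face/body shared latent component (0 = no
#'   sharing).
#' @param categories Category names (first two share the latent component).
#' @param cat_sd SD of the category mean patterns.
#' @param noise_sd Per-image noise SD.
#' @param seed Integer seed.
#' @return List with `features` (matrix), `labels`, and `shared` (the latent
#'   component vector).
#' @export
make_category_features <- function(n_per_cat = 6, n_units = 40, lambda = 0,
                                   categories = c("face", "body", "animal",
                                                  "house", "object", "tool"),
                                   cat_sd = 1, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n_cat <- length(categories)
  mu <- matrix(stats::rnorm(n_cat * n_units, sd = cat_sd), n_cat, n_units)
  shared <- stats::rnorm(n_units)
  labels <- rep(categories, each = n_per_cat)
  X <- matrix(stats::rnorm(n_per_cat * n_cat * n_units, sd = noise_sd),
              n_per_cat * n_cat, n_units)
  for (i in seq_along(labels)) {
    ci <- match(labels[i], categories)
    X[i, ] <- X[i, ] + mu[ci, ]
    if (ci <= 2) X[i, ] <- X[i, ] + lambda * shared
  }
  list(features = X, labels = labels, shared = shared)
}
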