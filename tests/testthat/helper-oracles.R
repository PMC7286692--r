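# Independent oracles used across test files. Each is a direct, slow
# realisation of a definition, kept free of the package's implementation
# paths.

# Benjamini-Hochberg step-up by direct definition: find the largest k with
# p_(k) <= k q / m and reject every p at or below p_(k).
oracle_bh_step_up <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the |d| ranks (no ties, no zeros assumed).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Two-pass separable linear interpolation of a grid at one target point.
oracle_bilinear_point <- function(xs, ys, values, xt, yt) {
  ix <- max(which(xs <= xt + 1e-12)); ix <- min(ix, length(xs) - 1)
  iy <- max(which(ys <= yt + 1e-12)); iy <- min(iy, length(ys) - 1)
  tx <- (xt - xs[ix]) / (xs[ix + 1] - xs[ix])
  ty <- (yt - ys[iy]) / (ys[iy + 1] - ys[iy])
  v1 <- values[iy, ix] * (1 - tx) + values[iy, ix + 1] * tx
  v2 <- values[iy + 1, ix] * (1 - tx) + values[iy + 1, ix + 1] * tx
  v1 * (1 - ty) + v2 * ty
}

# Spearman rank correlation of two vectors from first principles.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Least-squares Procrustes distance after centering, scaling to unit norm,
# and optimal rotation/reflection.
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  A <- A / norm(A, "F"); B <- B / norm(B, "F")
  s <- svd(crossprod(B, A))
  sqrt(max(0, 2 - 2 * sum(s$d)))
}

# Log-log spectral slope of an image via the radially binned periodogram.
spectral_slope <- function(im) {
  n <- nrow(im)
  P <- Mod(stats::fft(im - mean(im)))^2
  fx <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  keep <- fr > 0 & fr <= 0.5
  bins <- cut(log(fr[keep]), breaks = 12)
  lp <- tapply(log(P[keep]), bins, mean)
  lf <- tapply(log(fr[keep]), bins, mean)
  ok <- is.finite(lp) & is.finite(lf)
  unname(stats::coef(stats::lm(lp[ok] ~ lf[ok]))[2])
}

# Small standard array + session builders used by several files.
tiny_array <- function(n = 1, center = c(0.5, 0.5), sigma = 1, ...) {
  array_model(n_channels = n, center_deg = center, jitter_sd_deg = 0,
              seed = 1, rf_sigma_deg = sigma, ...)
}

face_only_scene <- function(at = c(0, 0), id = "face_scene", r = 1.5) {
  scene_spec(id, list(region("face", at, c(r, r))))
}
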