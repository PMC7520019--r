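# independent oracles used across test files

# plane fit via singular value decomposition of the centered coordinates
svd_plane_oracle <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3], rms = sv$d[3] / sqrt(nrow(pts)))
}

# ICC(A,1) from the ANOVA sums of squares computed by explicit double loops
icc_bruteforce_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - gm)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
    }
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# consistency-form ICC (two-way, single measures): invariant under
# constant reader shifts; used only as a comparison oracle
icc_consistency_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  mse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + gm)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# analytic centreline of a bowed shaft: circular arc with zero deflection at
# the ends and `bow` at midshaft
arc_centerline_oracle <- function(z, length, bow) {
  half <- length / 2
  R <- (bow^2 + half^2) / (2 * bow)
  cbind(0, sqrt(R^2 - (z - half)^2) - sqrt(R^2 - half^2), z)
}

tls_line_direction <- function(pts) {
  d <- prcomp(pts)$rotation[, 1]
  if (d[3] < 0) d <- -d
  d
}
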