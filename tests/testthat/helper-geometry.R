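# geometric fixtures built in code

cube_mesh <- function(origin = c(0, 0, 0), size = 1) {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))) * size
  v <- sweep(v, 2, origin, "+")
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 8, 7), c(5, 6, 8),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 8, 4), c(3, 7, 8),   # y = 1
    c(1, 7, 3), c(1, 5, 7),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = 1
  surface_mesh(v, f)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

rand_rotation <- function() {
  a <- stats::runif(3, -pi, pi)
  rot_z(a[1]) %*% rot_x(a[2]) %*% rot_z(a[3])
}

transform_patches <- function(patches, rotation, translation) {
  lapply(patches, function(p) {
    labeled_patch(p$region,
                  sweep(p$points %*% t(rotation), 2, translation, "+"))
  })
}

sort_rows <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

# orthonormal basis of the plane perpendicular to a unit vector
orth_complement <- function(n) {
  qr.Q(qr(matrix(n, 3, 1)), complete = TRUE)[, 2:3]
}

angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# points sampled on the plane through `centroid` with the given unit normal
plane_points <- function(n, centroid, normal, extent = 10, noise_sd = 0) {
  e1 <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  u <- stats::runif(n, -extent, extent)
  w <- stats::runif(n, -extent, extent)
  pts <- outer(u, e1) + outer(w, e2)
  pts <- sweep(pts, 2, centroid, "+")
  if (noise_sd > 0) pts <- pts + outer(stats::rnorm(n, 0, noise_sd), normal)
  pts
}
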