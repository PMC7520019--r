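#' Total-least-squares (PCA) plane fit to a point set
#'
#' Fits the plane minimising the sum of squared orthogonal distances to the
#' points: the plane through the centroid whose normal is the least-variance
#' principal direction of the centered coordinates. This is the plane each
#' brushed articular region is summarised by before its slope is measured.
#'
#' The pre-orientation sign of the normal is arbitrary; [compute_slope()]
#' re-orients it towards the proximal hemisphere before any angle is taken.
#'
#' @param points Numeric N x 3 matrix (mm), N >= 3, not all collinear.
#' @return An object of class `fitted_plane`: `centroid` (mm), unit `normal`,
#'   `rms_residual` (mm, root-mean-square orthogonal distance), `n_points`.
#' @details A patch whose two smallest scatter eigenvalues tie (a rotationally
#'   ambiguous, rod-like point set) has no unique least-squares plane; the fit
#'   fails rather than silently picking a direction, since a slope measured
#'   from it would be meaningless.
#' @examples
#' pts <- cbind(runif(50), runif(50), 5)
#' fit_plane(pts)$normal
#' @export
fit_plane <- function(points) {
  if (inherits(points, "labeled_patch")) points <- points$points
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be N x 3", call. = FALSE)
  n <- nrow(points)
  if (n < 3L) stop("plane fit needs at least 3 points, got ", n, call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sc <- crossprod(x) / n                 # mean scatter; eigenvalues = variances
  e <- eigen(sc, symmetric = TRUE)       # values in decreasing order
  ev <- e$values
  scale <- max(ev[1], 1e-300)
  if (ev[2] / scale <= 1e-12) {
    stop("rank-deficient point set (collinear or duplicate points): ",
         "second principal variance is ", format(ev[2]),
         "; plane fit is ill-posed", call. = FALSE)
  }
  if ((ev[2] - ev[3]) / scale <= 1e-12) {
    stop("degenerate plane fit: the two smallest scatter eigenvalues tie (",
         format(ev[3]), " vs ", format(ev[2]),
         "); the least-squares plane is rotationally ambiguous", call. = FALSE)
  }
  normal <- e$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  lam3 <- max(ev[3], 0)
  if (lam3 < 1e-12 * scale) lam3 <- 0      # below the eigen-solver noise floor
  structure(list(centroid = ctr, normal = normal,
                 rms_residual = sqrt(lam3), n_points = n),
            class = "fitted_plane")
}

#' @export
print.fitted_plane <- function(x, ...) {
  cat(sprintf("<fitted_plane> n = %d, normal = (%.4f, %.4f, %.4f), rms = %.4g mm\n",
              x$n_points, x$normal[1], x$normal[2], x$normal[3], x$rms_residual))
  invisible(x)
}

#' Sum of squared orthogonal distances from points to a plane
#'
#' @param points N x 3 matrix.
#' @param centroid A point on the plane.
#' @param normal Plane normal (need not be unit; normalised internally).
#' @return Scalar sum of squared distances (mm^2).
#' @keywords internal
plane_sse <- function(points, centroid, normal) {
  normal <- normal / sqrt(sum(normal^2))
  d <- as.vector(sweep(as.matrix(points), 2, centroid) %*% normal)
  sum(d^2)
}
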