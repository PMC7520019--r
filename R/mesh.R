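#' Construct a triangle surface mesh
#'
#' A `surface_mesh` is the geometric substrate of every measurement in this
#' package: a triangle soup in millimetres, typically a segmented proximal
#' tibia. Meshes are not required to be watertight (segmentation output rarely
#' is); only cross-section slicing imposes local closedness.
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param units Unit tag; must be `"mm"`. CT segmentations are mm-native and
#'   silent unit drift is the main failure mode in the field, so anything else
#'   is refused.
#' @param clean If `TRUE`, merge duplicate vertices (within 1e-6 mm) and drop
#'   zero-area faces, warning with a count when faces are removed.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `units`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' mesh_extent(m)
#' @export
surface_mesh <- function(vertices, faces, units = "mm", clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (!identical(units, "mm")) {
    stop("mesh units must be \"mm\", got \"", units, "\"", call. = FALSE)
  }
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    stop("vertices and faces must have 3 columns", call. = FALSE)
  }
  if (nrow(vertices) < 1L || nrow(faces) < 1L) {
    stop("empty mesh: no vertices or no faces", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face index out of range [1, ", nrow(vertices), "]", call. = FALSE)
  }
  m <- structure(list(vertices = vertices, faces = faces, units = "mm"),
                 class = "surface_mesh")
  if (clean) m <- clean_mesh(m)
  if (nrow(m$vertices) < 4L || nrow(m$faces) < 4L) {
    stop("mesh must have at least 4 vertices and 4 faces after cleanup",
         call. = FALSE)
  }
  m
}

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices closer than `tol` are merged (coordinates are snapped to a grid of
#' pitch `tol`); faces with repeated vertices or zero area are removed with a
#' warning stating the count.
#'
#' @param mesh A `surface_mesh`.
#' @param tol Merge tolerance in mm.
#' @return The cleaned `surface_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f <- matrix(remap[mesh$faces], ncol = 3L)
  # degenerate: repeated vertex index or numerically zero area
  repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  a <- v2[f[, 2], , drop = FALSE] - v2[f[, 1], , drop = FALSE]
  b <- v2[f[, 3], , drop = FALSE] - v2[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  bad <- repeated | area2 < 1e-12
  if (any(bad)) {
    warning(sum(bad), " degenerate (zero-area) face",
            if (sum(bad) > 1L) "s" else "", " dropped", call. = FALSE)
    f <- f[!bad, , drop = FALSE]
  }
  structure(list(vertices = v2, faces = f, units = "mm"),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  ext <- mesh_extent(x)
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, extent ", paste(sprintf("%.1f", ext), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Axis-aligned bounding-box extent of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric length-3 vector of extents (mm) along x, y, z.
#' @export
mesh_extent <- function(mesh) {
  apply(mesh$vertices, 2, function(c) diff(range(c)))
}

#' Check a mesh is long enough for slope measurement
#'
#' Slope measurement needs at least `min_extent` mm of shaft (the axis fit
#' starts 150 mm distal to the joint line). Checked at pipeline entry, not at
#' load, so short meshes can still be inspected.
#'
#' @param mesh A `surface_mesh`.
#' @param min_extent Required extent along the longest bounding-box dimension, mm.
#' @return `mesh`, invisibly; errors if too short.
#' @keywords internal
assert_measurement_mesh <- function(mesh, min_extent = 150) {
  ext <- max(mesh_extent(mesh))
  if (ext < min_extent) {
    stop("mesh extent ", sprintf("%.1f", ext), " mm is shorter than the ",
         min_extent, " mm required for slope measurement", call. = FALSE)
  }
  invisible(mesh)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return The transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  structure(list(vertices = v, faces = mesh$faces, units = "mm"),
            class = "surface_mesh")
}

REGION_LEVELS <- c("medial_plateau", "medial_rim", "lateral_plateau", "lateral_rim")

#' Construct a labeled articular patch
#'
#' A patch is one of the four brushed articular regions (medial/lateral
#' plateau and rim) given as an explicit point set, optionally backed by
#' vertex indices into a mesh.
#'
#' @param region One of `"medial_plateau"`, `"medial_rim"`,
#'   `"lateral_plateau"`, `"lateral_rim"`.
#' @param points Numeric N x 3 matrix of mm coordinates, N >= 3, not all
#'   collinear.
#' @param vertex_indices Optional 1-based indices into the source mesh.
#' @return An object of class `labeled_patch`.
#' @export
labeled_patch <- function(region, points, vertex_indices = NULL) {
  region <- match.arg(region, REGION_LEVELS)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("patch points must be N x 3", call. = FALSE)
  if (nrow(points) < 3L) {
    stop("patch \"", region, "\" needs at least 3 points, got ", nrow(points),
         call. = FALSE)
  }
  ctr <- colMeans(points)
  sc <- crossprod(sweep(points, 2, ctr))
  ev <- eigen(sc, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9 * max(ev[1], 1e-300)) {
    stop("patch \"", region, "\" points are collinear; plane fit is ill-posed",
         call. = FALSE)
  }
  structure(list(region = region, points = points,
                 vertex_indices = vertex_indices),
            class = "labeled_patch")
}

#' @export
print.labeled_patch <- function(x, ...) {
  cat("<labeled_patch> ", x$region, ": ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Validate a set of four articular patches
#'
#' @param patches List of `labeled_patch`.
#' @return Named list (by region), errors on missing/duplicate regions.
#' @keywords internal
as_patch_set <- function(patches) {
  if (inherits(patches, "labeled_patch")) patches <- list(patches)
  regs <- vapply(patches, function(p) p$region, character(1))
  dup <- unique(regs[duplicated(regs)])
  if (length(dup)) {
    stop("duplicated region label: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(REGION_LEVELS, regs)
  if (length(missing)) {
    stop("missing region: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::setNames(patches, regs)[REGION_LEVELS]
}
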