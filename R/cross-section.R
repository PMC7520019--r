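#' Cross-section of a triangle mesh by a plane
#'
#' Intersects every triangle with the plane, chains the resulting segments
#' into closed boundary loops via shared-edge adjacency (exact, no coordinate
#' snapping), and summarises the shaft boundary: when several loops exist the
#' loop of largest absolute area is taken as the outer shaft contour and
#' inner loops (intramedullary voids, segmentation artifacts) are ignored.
#' Area is computed by the planar shoelace formula and the centroid as the
#' area-weighted polygon centroid, mapped back to 3D.
#'
#' @param mesh A [surface_mesh].
#' @param plane_point A point on the slicing plane (mm).
#' @param plane_normal Plane normal (normalised internally).
#' @param strict If `TRUE` (default), an open segment chain (a mesh hole
#'   crossing the plane) is a topology error naming the gap size. If `FALSE`,
#'   open chains are dropped and only closed loops are considered — used when
#'   probing near the articular end where detached patch islands may be cut.
#' @param station_offset Optional station label (mm distal from the articular
#'   reference point) recorded in the result.
#' @return An object of class `cross_section`: `station_offset`, `point`,
#'   `normal`, `polygon` (ordered loop, k x 3, mm), `area` (mm^2), `centroid`
#'   (3D, on the slicing plane), `n_loops`.
#' @export
slice_mesh <- function(mesh, plane_point, plane_normal, strict = TRUE,
                       station_offset = NA_real_) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector(v %*% n) - sum(plane_point * n)
  # vertices exactly on the plane are nudged to the positive side so every
  # triangle has strictly signed corners; shared vertices stay consistent
  d[abs(d) < 1e-12] <- 1e-12
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  e12 <- s1 != s2; e23 <- s2 != s3; e31 <- s3 != s1
  crossing <- e12 | e23 | e31
  if (!any(crossing)) {
    stop(errorCondition(
      "slicing plane does not intersect the mesh (empty section)",
      class = c("tibslope_empty_section", "error", "condition")))
  }
  fc <- f[crossing, , drop = FALSE]
  e12 <- e12[crossing]; e23 <- e23[crossing]; e31 <- e31[crossing]
  nv <- nrow(v)
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  k12 <- ekey(fc[, 1], fc[, 2]); k23 <- ekey(fc[, 2], fc[, 3])
  k31 <- ekey(fc[, 3], fc[, 1])
  # each crossing face contributes exactly two crossed edges
  keyA <- ifelse(e12, k12, k23)
  keyB <- ifelse(e31, k31, k23)
  allkeys <- c(keyA, keyB)
  ukeys <- unique(allkeys)
  idA <- match(keyA, ukeys); idB <- match(keyB, ukeys)
  # intersection point of each unique crossed edge
  ua <- ukeys %/% (nv + 1); ub <- ukeys %% (nv + 1)
  t <- d[ua] / (d[ua] - d[ub])
  pts <- v[ua, , drop = FALSE] + t * (v[ub, , drop = FALSE] - v[ua, , drop = FALSE])
  # node adjacency: per edge-node, the partner node through each incident face
  m <- length(ukeys)
  deg <- tabulate(c(idA, idB), nbins = m)
  nb1 <- integer(m); nb2 <- integer(m)   # up to two neighbours per node
  cnt <- integer(m)
  add_nb <- function(i, j) {
    ci <- cnt[i] + 1L
    if (ci == 1L) nb1[i] <<- j else if (ci == 2L) nb2[i] <<- j else
      stop("non-manifold section: edge shared by >2 crossing faces",
           call. = FALSE)
    cnt[i] <<- ci
  }
  for (q in seq_along(idA)) {
    add_nb(idA[q], idB[q])
    add_nb(idB[q], idA[q])
  }
  if (strict && any(deg == 1L)) {
    open_nodes <- which(deg == 1L)
    gap <- if (length(open_nodes) >= 2L) {
      min(stats::dist(pts[open_nodes, , drop = FALSE]))
    } else NA_real_
    stop(errorCondition(
      sprintf(paste0("unclosable section loop: mesh hole crossing the ",
                     "slicing plane (smallest gap %.3g mm)"), gap),
      class = c("tibslope_topology_error", "error", "condition")))
  }
  visited <- logical(m)
  visited[deg != 2L] <- TRUE             # only chain closed loops
  loops <- list()
  for (start in seq_len(m)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    closed <- FALSE
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (nb1[cur] != prev) nb1[cur] else nb2[cur]
      if (nxt == start) { closed <- TRUE; break }
      if (visited[nxt]) break            # guard against degenerate 2-cycles
      prev <- cur; cur <- nxt
    }
    if (closed && length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (!length(loops)) {
    stop(errorCondition("no closed boundary loop in section",
                        class = c("tibslope_empty_section", "error",
                                  "condition")))
  }
  # in-plane basis
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  loop_stats <- lapply(loops, function(lp) {
    p <- pts[lp, , drop = FALSE]
    rel <- sweep(p, 2, plane_point)
    u <- as.vector(rel %*% e1); w <- as.vector(rel %*% e2)
    j <- c(seq_along(u)[-1], 1L)
    cr <- u * w[j] - u[j] * w
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(list(area = 0, centroid = NULL))
    cu <- sum((u + u[j]) * cr) / (6 * a)
    cw <- sum((w + w[j]) * cr) / (6 * a)
    list(area = abs(a),
         centroid = plane_point + cu * e1 + cw * e2,
         polygon = p)
  })
  areas <- vapply(loop_stats, function(x) x$area, numeric(1))
  if (all(areas == 0)) stop("degenerate (zero-area) section", call. = FALSE)
  best <- loop_stats[[which.max(areas)]]
  structure(list(station_offset = station_offset,
                 point = as.numeric(plane_point), normal = n,
                 polygon = best$polygon, area = best$area,
                 centroid = best$centroid, n_loops = length(loops)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> area %.2f mm^2, centroid (%.2f, %.2f, %.2f)%s\n",
              x$area, x$centroid[1], x$centroid[2], x$centroid[3],
              if (is.na(x$station_offset)) "" else
                sprintf(", station %.0f mm", x$station_offset)))
  invisible(x)
}
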