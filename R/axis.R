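#' Fit the 3D anatomical tibial axis from serial shaft cross-sections
#'
#' Reproduces the automatic axis construction used for 3D slope measurement:
#' an axial cross-section of the shaft is generated `start_offset` mm (default
#' 150) distal to the articular surface, then repeated in `step` mm (default
#' 5) increments proximally until a section's area exceeds
#' `area_factor` (default 1.6) times the first section's area; the axis is the
#' 3D total-least-squares line through the retained section centroids.
#'
#' Details of the construction:
#' \enumerate{
#'   \item The provisional long axis is the first principal component of all
#'     mesh vertices, oriented so the end with the larger mean cross-sectional
#'     area over its terminal 20 mm (the flaring metaphysis) is proximal.
#'   \item The articular reference point for the `start_offset` datum is the
#'     most proximal mesh vertex along the current slicing direction.
#'   \item The first section whose area strictly exceeds the threshold is
#'     discarded and iteration ends (`stop_reason = "area_threshold"`);
#'     running out of stations gives `stop_reason = "mesh_end"`. Equality with
#'     the threshold continues.
#'   \item With `refine_iterations > 0` the datum/section/fit cycle is
#'     repeated with slicing planes perpendicular to the fitted axis, removing
#'     the residual dependence on the provisional direction.
#' }
#'
#' @param mesh A [surface_mesh] of the segmented tibia (no fibula), extending
#'   at least `start_offset` mm along its long axis.
#' @param start_offset First station, mm distal from the articular reference
#'   point. Default 150.
#' @param step Station spacing, mm. Default 5.
#' @param area_factor Stop threshold as a multiple of the first section area.
#'   Default 1.6.
#' @param refine_iterations Number of re-slicing passes perpendicular to the
#'   fitted axis. Default 1.
#' @return An object of class `anatomical_axis`: `point` (mm), unit
#'   `direction` (distal to proximal), `cross_sections` (most distal first),
#'   `rms_centroid_residual` (mm), `first_section_area` (mm^2), `stop_reason`,
#'   `datum_point`.
#' @examples
#' shaft <- generate_shaft(length = 200, radius = 15)
#' ax <- fit_axis(shaft)
#' ax$direction
#' @export
fit_axis <- function(mesh, start_offset = 150, step = 5, area_factor = 1.6,
                     refine_iterations = 1) {
  stopifnot(inherits(mesh, "surface_mesh"), start_offset > 0, step > 0,
            area_factor > 1, refine_iterations >= 0)
  v <- mesh$vertices
  ctr <- colMeans(v)
  pc <- eigen(crossprod(sweep(v, 2, ctr)), symmetric = TRUE)$vectors[, 1]
  dir <- orient_provisional(mesh, pc / sqrt(sum(pc^2)))

  sections <- NULL; stop_reason <- NULL
  point <- NULL; datum_point <- NULL
  for (pass in seq_len(1L + refine_iterations)) {
    proj <- as.vector(v %*% dir)
    available <- max(proj) - min(proj)
    if (available < start_offset) {
      stop(sprintf(paste0("mesh too short for axis fitting: %.1f mm available ",
                          "along the shaft, %.1f mm required"),
                   available, start_offset), call. = FALSE)
    }
    datum_point <- v[which.max(proj), ]
    offsets <- seq(start_offset, step, by = -step)
    sections <- list()
    stop_reason <- "mesh_end"
    first_area <- NA_real_
    for (off in offsets) {
      cs <- tryCatch(
        slice_mesh(mesh, datum_point - off * dir, dir, station_offset = off),
        tibslope_empty_section = function(e) NULL)
      if (is.null(cs)) break
      if (is.na(first_area)) first_area <- cs$area
      if (cs$area > area_factor * first_area) {
        stop_reason <- "area_threshold"
        break
      }
      sections[[length(sections) + 1L]] <- cs
    }
    if (length(sections) < 2L) {
      stop("degenerate axis: fewer than 2 retained cross-sections",
           call. = FALSE)
    }
    cents <- do.call(rbind, lapply(sections, function(s) s$centroid))
    point <- colMeans(cents)
    cpc <- eigen(crossprod(sweep(cents, 2, point)), symmetric = TRUE)$vectors[, 1]
    cpc <- cpc / sqrt(sum(cpc^2))
    if (sum(cpc * dir) < 0) cpc <- -cpc
    dir <- cpc
  }
  cents <- do.call(rbind, lapply(sections, function(s) s$centroid))
  rel <- sweep(cents, 2, point)
  perp <- rel - as.vector(rel %*% dir) %o% dir
  rms <- sqrt(mean(rowSums(perp^2)))
  structure(list(point = point, direction = dir, cross_sections = sections,
                 rms_centroid_residual = rms,
                 first_section_area = sections[[1]]$area,
                 stop_reason = stop_reason, datum_point = datum_point,
                 start_offset = start_offset, step = step,
                 area_factor = area_factor,
                 refine_iterations = refine_iterations),
            class = "anatomical_axis")
}

# Orient the provisional direction so it points to the (proximal) end with
# the larger mean section area over its terminal 20 mm.
orient_provisional <- function(mesh, dir, probe_depth = 20, probe_step = 5) {
  proj <- as.vector(mesh$vertices %*% dir)
  lo <- min(proj); hi <- max(proj)
  probe <- function(vals) {
    areas <- vapply(vals, function(pv) {
      cs <- tryCatch(
        slice_mesh(mesh, dir * pv, dir, strict = FALSE),
        error = function(e) NULL)
      if (is.null(cs)) NA_real_ else cs$area
    }, numeric(1))
    mean(areas, na.rm = TRUE)
  }
  offs <- seq(probe_step, probe_depth, by = probe_step)
  a_hi <- probe(hi - offs)
  a_lo <- probe(lo + offs)
  if (is.finite(a_hi) && is.finite(a_lo)) {
    if (a_lo > a_hi * (1 + 1e-9)) return(-dir)
    if (a_hi > a_lo * (1 + 1e-9)) return(dir)
  }
  # symmetric shaft: no intrinsic proximal end; canonicalise the sign so the
  # result is deterministic (largest-magnitude component positive)
  k <- which.max(abs(dir))
  if (dir[k] < 0) -dir else dir
}

#' @export
print.anatomical_axis <- function(x, ...) {
  cat(sprintf(paste0("<anatomical_axis> direction (%.4f, %.4f, %.4f), ",
                     "%d sections, rms %.4g mm, stop: %s\n"),
              x$direction[1], x$direction[2], x$direction[3],
              length(x$cross_sections), x$rms_centroid_residual, x$stop_reason))
  invisible(x)
}

#' Tidy the cross-section stations of a fitted axis
#'
#' @param x An `anatomical_axis`.
#' @param ... Unused.
#' @return A tibble with one row per retained station: `station_offset`,
#'   `area`, `centroid_x/y/z`.
#' @method tidy anatomical_axis
#' @export
tidy.anatomical_axis <- function(x, ...) {
  dplyr::bind_rows(lapply(x$cross_sections, function(s) {
    tibble::tibble(station_offset = s$station_offset, area = s$area,
                   centroid_x = s$centroid[1], centroid_y = s$centroid[2],
                   centroid_z = s$centroid[3])
  }))
}

#' Station area profile plot for a fitted axis
#'
#' Shows the retained cross-section areas against their station offsets with
#' the stop threshold (`area_factor` times the first area) as a reference
#' line — the diagnostic view of the metaphyseal stopping rule.
#'
#' @param object An `anatomical_axis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anatomical_axis
#' @export
autoplot.anatomical_axis <- function(object, ...) {
  df <- tidy.anatomical_axis(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$station_offset, y = .data$area)) +
    ggplot2::geom_hline(yintercept = object$area_factor * object$first_section_area,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "station (mm, relative to articular datum)",
                  y = expression(paste("section area (", mm^2, ")")),
                  title = sprintf("shaft cross-section profile (stop: %s)",
                                  object$stop_reason)) +
    ggplot2::theme_minimal()
}
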