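unit3 <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the measurement coordinate frame
#'
#' The slope is a sagittal-plane angle, so a mediolateral (sagittal-normal)
#' direction must be fixed. The package's convention: mediolateral is the
#' direction from the lateral to the medial plateau centroid, orthogonalised
#' against the anatomical axis; anteroposterior completes a right-handed triad
#' (`longitudinal x mediolateral`), flipped together with mediolateral if
#' needed so it points anteriorly. Anterior is disambiguated from the offset
#' of the most proximal retained shaft-section centroid relative to the
#' midpoint of the plateau centroids (the tibial shaft and tubercle lie
#' anterior to the plateau centre). A user-supplied mediolateral override is
#' accepted and recorded in the frame provenance.
#'
#' @param axis An [fit_axis()] result.
#' @param patches Named list of four [labeled_patch] (needed unless
#'   `override_mediolateral` and `anterior_hint` are both given).
#' @param override_mediolateral Optional length-3 vector replacing the
#'   inter-plateau-centroid direction (orthogonalised and renormalised).
#' @param anterior_hint Optional length-3 vector forcing the anterior
#'   hemisphere (for pathological shapes).
#' @return An object of class `coordinate_frame`: `origin`, unit vectors
#'   `longitudinal` (distal to proximal), `mediolateral`, `anteroposterior`
#'   (posterior to anterior), `provenance`.
#' @export
build_frame <- function(axis, patches = NULL, override_mediolateral = NULL,
                        anterior_hint = NULL) {
  stopifnot(inherits(axis, "anatomical_axis"))
  long <- unit3(axis$direction)
  if (!is.null(override_mediolateral)) {
    raw <- as.numeric(override_mediolateral)
    if (length(raw) != 3L) stop("override must be a length-3 vector", call. = FALSE)
    ang <- acos(min(1, abs(sum(unit3(raw) * long))))
    if (ang < pi / 180) {
      stop("mediolateral override is within 1 degree of the anatomical axis",
           call. = FALSE)
    }
    provenance <- "user_supplied"
  } else {
    if (is.null(patches)) {
      stop("patches are required unless override_mediolateral is supplied",
           call. = FALSE)
    }
    ps <- as_patch_set(patches)
    cm <- colMeans(ps$medial_plateau$points)
    cl <- colMeans(ps$lateral_plateau$points)
    raw <- cm - cl
    if (sqrt(sum(raw^2)) < 1) {
      stop("degenerate frame: plateau centroids within 1 mm of each other",
           call. = FALSE)
    }
    provenance <- "derived_from_patches"
  }
  ml <- raw - sum(raw * long) * long
  if (sqrt(sum(ml^2)) < 1e-9) {
    stop("mediolateral direction is parallel to the anatomical axis",
         call. = FALSE)
  }
  ml <- unit3(ml)
  ap <- cross3(long, ml)                  # right-handed: det[ml, ap, long] = +1
  # anterior disambiguation
  ant <- NULL
  if (!is.null(anterior_hint)) {
    ant <- as.numeric(anterior_hint)
  } else if (!is.null(patches)) {
    ps <- as_patch_set(patches)
    mid <- (colMeans(ps$medial_plateau$points) +
            colMeans(ps$lateral_plateau$points)) / 2
    top <- axis$cross_sections[[length(axis$cross_sections)]]$centroid
    ant <- top - mid
  }
  # flip only on a clear posterior indicator; a numerically null offset
  # (exactly symmetric phantom) keeps the default orientation
  if (!is.null(ant) && sum(ant * ap) < -1e-9) {
    ap <- -ap
    ml <- -ml                             # keep the triad right-handed
  }
  origin <- axis$point
  structure(list(origin = origin, longitudinal = long, mediolateral = ml,
                 anteroposterior = ap, provenance = provenance),
            class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat("<coordinate_frame> (", x$provenance, ")\n", sep = "")
  for (nm in c("longitudinal", "mediolateral", "anteroposterior")) {
    cat(sprintf("  %-16s (%.4f, %.4f, %.4f)\n", nm, x[[nm]][1], x[[nm]][2],
                x[[nm]][3]))
  }
  invisible(x)
}

#' Signed sagittal slope of a fitted articular plane
#'
#' The tibial slope is the angle between the anatomical axis and the plane
#' normal after both are projected into the sagittal plane (their mediolateral
#' components removed). The plane normal is first re-oriented to the proximal
#' hemisphere, making the computation independent of the stored normal sign.
#' Positive slope means the projected normal leans posterior of the projected
#' axis — a surface normal tilts towards its downhill side, so a plateau
#' tilted posterior-inferior (the clinical posterior slope) gives a positive
#' angle, matching the positive slopes reported for normal knees.
#'
#' @param plane A [fit_plane()] result.
#' @param axis An [fit_axis()] result (or any object with `$direction`).
#' @param frame A [build_frame()] result.
#' @param region Optional region label carried into the result.
#' @return An object of class `slope_result`: `region`, `slope_deg` in
#'   (-90, 90), `plane`, `frame`.
#' @export
compute_slope <- function(plane, axis, frame, region = NA_character_) {
  stopifnot(inherits(plane, "fitted_plane"), inherits(frame, "coordinate_frame"))
  n <- unit3(plane$normal)
  long <- frame$longitudinal
  if (sum(n * long) < 0) n <- -n          # proximal hemisphere fix
  ns <- n - sum(n * frame$mediolateral) * frame$mediolateral
  if (sqrt(sum(ns^2)) < 1e-6) {
    stop("degenerate projection: plane normal is parallel to the ",
         "mediolateral direction", call. = FALSE)
  }
  ns <- unit3(ns)
  # posterior lean of the projected normal = posterior slope = positive
  slope <- atan2(-sum(ns * frame$anteroposterior), sum(ns * long)) * 180 / pi
  structure(list(region = region, slope_deg = slope, plane = plane,
                 frame = frame),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("<slope_result> %s: %.2f deg\n",
              if (is.na(x$region)) "(unlabelled)" else x$region, x$slope_deg))
  invisible(x)
}

#' Measurement configuration
#'
#' Bundles the tunable parameters of the pipeline with their standard
#' defaults: first station 150 mm distal to the joint line, 5 mm steps, stop
#' at 1.6 times the first section area, one axis refinement pass.
#'
#' @param start_offset,step,area_factor,refine_iterations See [fit_axis()].
#' @param override_mediolateral,anterior_hint See [build_frame()].
#' @return A named list of class `measure_config`.
#' @export
measure_config <- function(start_offset = 150, step = 5, area_factor = 1.6,
                           refine_iterations = 1,
                           override_mediolateral = NULL,
                           anterior_hint = NULL) {
  structure(list(start_offset = start_offset, step = step,
                 area_factor = area_factor,
                 refine_iterations = refine_iterations,
                 override_mediolateral = override_mediolateral,
                 anterior_hint = anterior_hint),
            class = "measure_config")
}

#' Measure the 3D tibial slope of all four articular regions
#'
#' Runs the full pipeline on one tibia: anatomical-axis fit from serial shaft
#' cross-sections, measurement frame construction, a total-least-squares plane
#' per brushed region, and the signed sagittal slope of each plane. The
#' computation is deterministic for fixed inputs and configuration.
#'
#' @param mesh A [surface_mesh] (>= 150 mm of shaft).
#' @param patches Four [labeled_patch] objects (list), one per region.
#' @param config A [measure_config()].
#' @return An object of class `slope_measurement` with `slopes` (a tibble:
#'   `region`, `slope_deg`, `rms_residual`, `n_points`), `planes`, `axis`,
#'   `frame`, `config`.
#' @examples
#' tib <- generate_tibia(tibia_spec())
#' res <- measure_all(tib$mesh, tib$patches)
#' res$slopes
#' @export
measure_all <- function(mesh, patches, config = measure_config()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  patches <- as_patch_set(patches)
  assert_measurement_mesh(mesh, min_extent = config$start_offset)
  axis <- with_stage("axis fitting",
    fit_axis(mesh, start_offset = config$start_offset, step = config$step,
             area_factor = config$area_factor,
             refine_iterations = config$refine_iterations))
  frame <- with_stage("frame construction",
    build_frame(axis, patches,
                override_mediolateral = config$override_mediolateral,
                anterior_hint = config$anterior_hint))
  planes <- lapply(patches, function(p) {
    with_stage(paste0("plane fit (", p$region, ")"), fit_plane(p$points))
  })
  slopes <- lapply(REGION_LEVELS, function(rg) {
    with_stage(paste0("slope (", rg, ")"),
               compute_slope(planes[[rg]], axis, frame, region = rg))
  })
  tbl <- tibble::tibble(
    region = REGION_LEVELS,
    slope_deg = vapply(slopes, function(s) s$slope_deg, numeric(1)),
    rms_residual = vapply(planes[REGION_LEVELS], function(p) p$rms_residual,
                          numeric(1)),
    n_points = vapply(planes[REGION_LEVELS], function(p) p$n_points,
                      numeric(1)))
  structure(list(slopes = tbl, planes = planes, axis = axis, frame = frame,
                 config = unclass(config)[!vapply(unclass(config), is.null,
                                                  logical(1))]),
            class = "slope_measurement")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(errorCondition(paste0("[", stage, "] ", conditionMessage(e)),
                        class = c("tibslope_stage_error", class(e))))
  })
}

#' @export
print.slope_measurement <- function(x, ...) {
  cat("<slope_measurement>\n")
  print(x$slopes)
  cat(sprintf("axis: %d sections, stop %s; frame: %s\n",
              length(x$axis$cross_sections), x$axis$stop_reason,
              x$frame$provenance))
  invisible(x)
}

#' @method tidy slope_measurement
#' @export
tidy.slope_measurement <- function(x, ...) x$slopes

#' @method glance slope_measurement
#' @export
glance.slope_measurement <- function(x, ...) {
  tibble::tibble(
    n_sections = length(x$axis$cross_sections),
    stop_reason = x$axis$stop_reason,
    axis_rms_mm = x$axis$rms_centroid_residual,
    frame_provenance = x$frame$provenance)
}

#' Per-region slope plot
#'
#' @param object A `slope_measurement`.
#' @param ... Unused.
#' @return A ggplot object showing the four signed slopes.
#' @method autoplot slope_measurement
#' @export
autoplot.slope_measurement <- function(object, ...) {
  df <- object$slopes
  df$region <- factor(df$region, levels = REGION_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$slope_deg)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::labs(x = NULL, y = "posterior slope (deg)",
                  title = "3D tibial slope by articular region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Construct a digitized 2D radiograph line
#'
#' Image convention: x grows anterior to posterior, y grows distal to
#' proximal.
#'
#' @param p1,p2 Length-2 endpoints (distinct).
#' @param role `"posterior_cortex"` or `"plateau_tangent"`.
#' @return An object of class `line2d`.
#' @export
line2d <- function(p1, p2, role = c("posterior_cortex", "plateau_tangent")) {
  role <- match.arg(role)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L) {
    stop("line endpoints must be length-2", call. = FALSE)
  }
  if (sqrt(sum((p2 - p1)^2)) < 1e-12) {
    stop("line endpoints coincide", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, role = role), class = "line2d")
}

#' Conventional radiographic posterior tibial slope
#'
#' The two-line lateral-radiograph measurement: the angle between a line
#' drawn along the posterior tibial cortex and a line along the horizontally
#' arranged densest zone at the top of the tibial head. Returned as the
#' posterior tibial slope: the signed angle between the plateau line and the
#' perpendicular to the cortex line, positive when the plateau drops
#' posteriorly (equivalently 90 degrees minus the acute angle between the two
#' lines, signed).
#'
#' @param cortex A [line2d] with role `posterior_cortex`.
#' @param plateau A [line2d] with role `plateau_tangent`.
#' @return Slope in degrees, positive posterior.
#' @examples
#' measure_2d_slope(line2d(c(0, 0), c(0, 100), "posterior_cortex"),
#'                  line2d(c(0, 100), c(50, 100), "plateau_tangent"))
#' @export
measure_2d_slope <- function(cortex, plateau) {
  stopifnot(inherits(cortex, "line2d"), inherits(plateau, "line2d"))
  cv <- cortex$p2 - cortex$p1
  if (cv[2] < 0) cv <- -cv                # cortex direction: distal -> proximal
  cv <- cv / sqrt(sum(cv^2))
  q <- c(cv[2], -cv[1])                   # perpendicular, pointing posterior
  p <- plateau$p2 - plateau$p1
  p <- p / sqrt(sum(p^2))
  if (sum(p * q) < 0) p <- -p             # plateau direction: towards posterior
  cross <- p[1] * q[2] - p[2] * q[1]
  dot <- sum(p * q)
  if (abs(dot) < 1e-9) {
    stop("lines are parallel: plateau parallel to the cortex implies a ",
         "physically impossible slope of +/-90 degrees", call. = FALSE)
  }
  atan2(cross, dot) * 180 / pi + 0   # normalise IEEE negative zero
}
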