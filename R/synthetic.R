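# Local RNG scope: run expr with a fixed seed, restoring the caller's RNG
# state afterwards so generators are deterministic without side effects.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic proximal tibia
#'
#' Parametric phantom standing in for a segmented patient CT: a tubular shaft
#' with a metaphyseal flare, optionally a sagittal bow, capped by four
#' idealised articular regions (medial/lateral plateau and rim) whose
#' ground-truth sagittal slopes and coronal tilts are exactly known by
#' construction. Default slopes are the observed population means for the
#' four regions (7.4, 7.6, 7.5, 8.1 degrees).
#'
#' @param shaft_length Shaft length, mm (>= 160 so the 150 mm axis start
#'   offset is reachable). Default 200.
#' @param shaft_radius Diaphyseal radius, mm. Default 15.
#' @param flare_radius Radius at the proximal end of the metaphyseal flare,
#'   mm. Default 35.
#' @param flare_length Length of the flare, mm. Default 40.
#' @param bow Sagittal centreline deflection (circular arc), mm. Default 0.
#' @param slopes Named or positional numeric vector of 4 ground-truth sagittal
#'   slopes, degrees, order medial_plateau, medial_rim, lateral_plateau,
#'   lateral_rim; each in (-20, 25).
#' @param coronal_tilts Ground-truth coronal tilts (rotation about the
#'   anteroposterior axis), degrees, same order. Default 0.
#' @param plateau_offset_ml Mediolateral plateau-centre offset, mm (medial at
#'   +x). Default 25.
#' @param plateau_offset_ap Anteroposterior plateau-centre offset, mm
#'   (negative = posterior, placing the shaft/tubercle anterior to the
#'   plateau centre as in vivo). Default -5.
#' @param plateau_radius Radius of the plateau disc, mm. Default 11.
#' @param rim_inner,rim_outer Inner/outer radius of the rim annulus, mm.
#'   Defaults 12.5 and 17.
#' @param plateau_depth Depth of the shallow plateau concavity, mm (symmetric,
#'   so the best-fit plane stays the specified tilted plane). Default 0.8.
#' @param rim_elevation Elevation of the rim band above the plateau centre,
#'   mm ("the outermost, elevated portion"). Default 1.5.
#' @param noise_sd SD of Gaussian vertex noise, mm. Default 0.
#' @param noise_along_normals If `TRUE`, noise displaces vertices along their
#'   normals (emulating segmentation surface error); default `FALSE`
#'   (isotropic, simpler to analyse).
#' @param segments Circumferential tessellation of the shaft. Default 64.
#' @param ring_spacing Axial ring spacing of the shaft, mm. Default 2.5.
#' @param region_segments,region_rings Tessellation of each articular region.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A list of class `tibia_spec`.
#' @export
tibia_spec <- function(shaft_length = 200, shaft_radius = 15,
                       flare_radius = 35, flare_length = 40, bow = 0,
                       slopes = c(medial_plateau = 7.4, medial_rim = 7.6,
                                  lateral_plateau = 7.5, lateral_rim = 8.1),
                       coronal_tilts = c(0, 0, 0, 0),
                       plateau_offset_ml = 25, plateau_offset_ap = -5,
                       plateau_radius = 11, rim_inner = 12.5, rim_outer = 17,
                       plateau_depth = 0.8, rim_elevation = 1.5,
                       noise_sd = 0, noise_along_normals = FALSE,
                       segments = 64, ring_spacing = 2.5,
                       region_segments = 48, region_rings = 6, seed = 1) {
  slopes <- stats::setNames(as.numeric(slopes), REGION_LEVELS)
  coronal_tilts <- stats::setNames(as.numeric(coronal_tilts), REGION_LEVELS)
  if (shaft_length < 160) {
    stop("shaft_length must be >= 160 mm so the 150 mm axis start offset is ",
         "reachable", call. = FALSE)
  }
  if (any(slopes <= -20 | slopes >= 25)) {
    stop("ground-truth slopes must lie in (-20, 25) degrees", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (rim_inner >= rim_outer) stop("rim_inner must be < rim_outer", call. = FALSE)
  if (rim_outer > plateau_offset_ml) {
    stop("rim band wider than the condyle: rim_outer (", rim_outer,
         ") exceeds the plateau offset (", plateau_offset_ml, ")",
         call. = FALSE)
  }
  if (flare_radius < shaft_radius || flare_length >= shaft_length) {
    stop("inconsistent flare geometry", call. = FALSE)
  }
  structure(as.list(environment()), class = "tibia_spec")
}

# sagittal bow: circular-arc lateral-view deflection of the centreline,
# zero at both ends, maximal (= bow) at midshaft
bow_offset <- function(z, length, bow) {
  if (bow == 0) return(rep(0, length(z)))
  half <- length / 2
  R <- (bow^2 + half^2) / (2 * bow)
  sqrt(R^2 - (z - half)^2) - sqrt(R^2 - half^2)
}

#' Generate a shaft-only synthetic bone mesh
#'
#' Surface of revolution about a (possibly bowed) centreline with a constant
#' diaphyseal radius and an optional linear metaphyseal flare, capped at both
#' ends. Used as an analytic fixture for the axis-fitting machinery and as
#' the substrate of [generate_tibia()].
#'
#' @param length Shaft length, mm.
#' @param radius Diaphyseal radius, mm.
#' @param flare_radius Radius at the proximal (z = `length`) end; equal to
#'   `radius` for a plain cylinder.
#' @param flare_length Axial extent of the flare, mm (0 for none).
#' @param bow Sagittal (y) centreline deflection, mm, circular arc.
#' @param segments Circumferential segments.
#' @param ring_spacing Axial ring spacing, mm.
#' @return A [surface_mesh] with the distal end at z = 0 and the proximal end
#'   at z = `length`.
#' @export
generate_shaft <- function(length = 200, radius = 15, flare_radius = radius,
                           flare_length = 0, bow = 0, segments = 64,
                           ring_spacing = 2.5) {
  g <- shaft_geometry(length, radius, flare_radius, flare_length, bow,
                      segments, ring_spacing)
  surface_mesh(g$vertices, g$faces)
}

shaft_geometry <- function(length, radius, flare_radius, flare_length, bow,
                           segments, ring_spacing) {
  nring <- max(2L, round(length / ring_spacing)) + 1L
  zs <- seq(0, length, length.out = nring)
  rflat <- length - flare_length
  rs <- ifelse(zs <= rflat | flare_length == 0, radius,
               radius + (flare_radius - radius) * (zs - rflat) / flare_length)
  ys <- bow_offset(zs, length, bow)
  th <- 2 * pi * seq(0, segments - 1) / segments
  ct <- cos(th); st <- sin(th)
  verts <- do.call(rbind, lapply(seq_along(zs), function(i) {
    cbind(rs[i] * ct, ys[i] + rs[i] * st, zs[i])
  }))
  ring_idx <- function(i) (i - 1L) * segments + seq_len(segments)
  quads <- do.call(rbind, lapply(seq_len(nring - 1L), function(i) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }))
  nv <- nrow(verts)
  c_bot <- nv + 1L; c_top <- nv + 2L
  verts <- rbind(verts, c(0, ys[1], zs[1]), c(0, ys[nring], zs[nring]))
  bot <- ring_idx(1L); top <- ring_idx(nring)
  caps <- rbind(cbind(c_bot, c(bot[-1], bot[1]), bot),
                cbind(c_top, top, c(top[-1], top[1])))
  list(vertices = verts, faces = rbind(quads, unname(caps)))
}

# rotation taking +z to the ground-truth region normal: a posterior slope
# theta tilts the surface posterior-inferior, leaning its upward normal
# posterior (-y); coronal tilt phi is a rotation about the anteroposterior
# axis. Applied sagittal-last so the sagittal projection of the normal makes
# exactly theta with the axis regardless of phi.
region_rotation <- function(slope_deg, coronal_deg) {
  th <- slope_deg * pi / 180
  ph <- coronal_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  ry <- rbind(c(cos(ph), 0, sin(ph)), c(0, 1, 0), c(-sin(ph), 0, cos(ph)))
  rx %*% ry
}

# concentric-ring sampling of a disc (r0 = 0) or annulus; all rings share the
# same segment count so the sampling is rotationally symmetric per ring, which
# keeps the centroid on the ring centre and the PCA plane exactly the
# constructed plane
region_geometry <- function(center, rot, r_inner, r_outer, depth, nseg, nring) {
  radii <- seq(r_inner, r_outer, length.out = nring + 1L)
  th <- 2 * pi * seq(0, nseg - 1) / nseg
  ct <- cos(th); st <- sin(th)
  rings <- list(); start <- integer(0)
  verts <- NULL
  if (r_inner == 0) {
    sag <- function(r) -depth * (1 - (r / r_outer)^2)
    verts <- rbind(c(0, 0, sag(0)))
    radii <- radii[-1]
  } else {
    sag <- function(r) 0 * r
  }
  for (r in radii) {
    start <- c(start, nrow(verts) %||% 0)
    verts <- rbind(verts, cbind(r * ct, r * st, sag(r)))
  }
  nvert0 <- if (r_inner == 0) 1L else 0L
  faces <- NULL
  if (r_inner == 0) {
    b <- 1L + seq_len(nseg)
    faces <- cbind(1L, b, c(b[-1], b[1]))
  }
  nrings_present <- length(radii)
  for (i in seq_len(nrings_present - 1L)) {
    a <- nvert0 + (i - 1L) * nseg + seq_len(nseg)
    b <- a + nseg
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces <- rbind(faces, cbind(a, a2, b2), cbind(a, b2, b))
  }
  world <- sweep(verts %*% t(rot), 2, center, "+")
  list(vertices = world, faces = unname(faces))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic proximal tibia with known ground truth
#'
#' Builds the mesh described by a [tibia_spec()], the four articular patch
#' labels (exactly the vertices of each constructed region; the intercondylar
#' region stays unlabelled), and the ground truth the construction encodes.
#' Fully deterministic for a fixed spec.
#'
#' @param spec A [tibia_spec()].
#' @return A list with `mesh` ([surface_mesh]), `patches` (named list of four
#'   [labeled_patch]), and `truth` (list: `axis_point`, `axis_direction`,
#'   `frame`, `slopes` tibble with `region`, `slope_deg`, `coronal_deg`).
#' @examples
#' tib <- generate_tibia(tibia_spec(slopes = c(5, 5, 5, 5)))
#' tib$mesh
#' @export
generate_tibia <- function(spec) {
  stopifnot(inherits(spec, "tibia_spec"))
  spec$slopes <- stats::setNames(as.numeric(spec$slopes), REGION_LEVELS)
  spec$coronal_tilts <- stats::setNames(as.numeric(spec$coronal_tilts),
                                        REGION_LEVELS)
  sh <- shaft_geometry(spec$shaft_length, spec$shaft_radius, spec$flare_radius,
                       spec$flare_length, spec$bow, spec$segments,
                       spec$ring_spacing)
  verts <- sh$vertices
  faces <- sh$faces
  patches <- list()
  plateau_z <- spec$shaft_length + 1.0
  rim_z <- plateau_z + spec$rim_elevation
  for (rg in REGION_LEVELS) {
    medial <- grepl("^medial", rg)
    is_rim <- grepl("rim$", rg)
    center <- c(if (medial) spec$plateau_offset_ml else -spec$plateau_offset_ml,
                spec$plateau_offset_ap,
                if (is_rim) rim_z else plateau_z)
    rot <- region_rotation(spec$slopes[[rg]], spec$coronal_tilts[[rg]])
    geo <- if (is_rim) {
      region_geometry(center, rot, spec$rim_inner, spec$rim_outer, 0,
                      spec$region_segments, spec$region_rings)
    } else {
      region_geometry(center, rot, 0, spec$plateau_radius, spec$plateau_depth,
                      spec$region_segments, spec$region_rings)
    }
    off <- nrow(verts)
    patches[[rg]] <- off + seq_len(nrow(geo$vertices))
    verts <- rbind(verts, geo$vertices)
    faces <- rbind(faces, geo$faces + off)
  }
  if (spec$noise_sd > 0) {
    verts <- with_seed(spec$seed, {
      if (spec$noise_along_normals) {
        vn <- vertex_normals(verts, faces)
        verts + vn * stats::rnorm(nrow(verts), 0, spec$noise_sd)
      } else {
        verts + matrix(stats::rnorm(length(verts), 0, spec$noise_sd),
                       ncol = 3L)
      }
    })
  }
  mesh <- surface_mesh(verts, faces, clean = FALSE)
  patch_objs <- lapply(REGION_LEVELS, function(rg) {
    idx <- patches[[rg]]
    labeled_patch(rg, mesh$vertices[idx, , drop = FALSE], vertex_indices = idx)
  })
  truth <- list(
    axis_point = c(0, 0, spec$shaft_length / 2),
    axis_direction = c(0, 0, 1),
    frame = list(mediolateral = c(1, 0, 0), anteroposterior = c(0, 1, 0),
                 longitudinal = c(0, 0, 1)),
    slopes = tibble::tibble(region = REGION_LEVELS,
                            slope_deg = unname(spec$slopes[REGION_LEVELS]),
                            coronal_deg = unname(spec$coronal_tilts[REGION_LEVELS])))
  list(mesh = mesh, patches = as_patch_set(patch_objs), truth = truth)
}

vertex_normals <- function(verts, faces) {
  fn <- face_normals(verts, faces)
  idx <- c(faces[, 1], faces[, 2], faces[, 3])
  agg <- rowsum(rbind(fn, fn, fn), idx)
  vn <- matrix(0, nrow(verts), 3L)
  vn[as.integer(rownames(agg)), ] <- agg
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Simulate a two-or-more-reader reliability study
#'
#' Generates `n_subjects` independent synthetic tibiae with per-subject true
#' slopes drawn from a normal population, measures each through the full 3D
#' pipeline, and derives per-reader values under a perturbation model:
#' \describe{
#'   \item{`"noise"`}{each reader's value is the pipeline measurement plus
#'     independent additive Gaussian reader noise (`reader_noise_sd`). Under
#'     this model the expected absolute-agreement ICC is
#'     `subject_sd^2 / (subject_sd^2 + reader_noise_sd^2)`.}
#'   \item{`"patch_jitter"`}{each reader re-fits the region planes after a
#'     reader-specific perturbation of the brushed patch (random boundary
#'     erosion and subsampling), emulating brushing variability; additive
#'     noise is applied on top if `reader_noise_sd > 0`.}
#' }
#' The axis and frame are fitted once per subject (they are automatic, not
#' reader-dependent). Deterministic for a fixed seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_readers Number of readers (>= 2). Default 2.
#' @param subject_mean,subject_sd Population mean and SD of the per-subject
#'   base slope, degrees. Defaults 7.65 and 4.
#' @param region_offsets Fixed per-region offsets added to the base slope,
#'   degrees (defaults reproduce the observed regional means).
#' @param reader_noise_sd Additive per-reader measurement noise SD, degrees.
#'   Default 1.
#' @param model Perturbation model, `"noise"` or `"patch_jitter"`.
#' @param erosion_range For `"patch_jitter"`: range of the kept-fraction of
#'   patch points per reader. Default c(0.6, 0.95).
#' @param base_spec A [tibia_spec()] providing the anatomy; its slopes are
#'   overridden per subject.
#' @param seed RNG seed.
#' @return A list: `ratings` (named list of [as_ratings_matrix()] matrices,
#'   one per region), `long` (tibble: subject, reader, region, slope_deg),
#'   `truth` (tibble of per-subject true slopes).
#' @export
generate_reader_study <- function(n_subjects, n_readers = 2,
                                  subject_mean = 7.65, subject_sd = 4,
                                  region_offsets = c(medial_plateau = -0.25,
                                                     medial_rim = -0.05,
                                                     lateral_plateau = -0.15,
                                                     lateral_rim = 0.45),
                                  reader_noise_sd = 1,
                                  model = c("noise", "patch_jitter"),
                                  erosion_range = c(0.6, 0.95),
                                  base_spec = tibia_spec(),
                                  seed = 1) {
  model <- match.arg(model)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (n_readers < 2) stop("n_readers must be >= 2", call. = FALSE)
  region_offsets <- stats::setNames(as.numeric(region_offsets), REGION_LEVELS)
  draws <- with_seed(seed, list(
    base = stats::rnorm(n_subjects, subject_mean, subject_sd),
    mesh_seeds = sample.int(.Machine$integer.max - 1L, n_subjects),
    noise = array(stats::rnorm(n_subjects * n_readers * 4, 0, 1),
                  dim = c(n_subjects, n_readers, 4)),
    keep_frac = matrix(stats::runif(n_subjects * n_readers,
                                    erosion_range[1], erosion_range[2]),
                       n_subjects, n_readers),
    jitter_seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                     n_subjects * n_readers),
                          n_subjects, n_readers)))
  vals <- array(NA_real_, dim = c(n_subjects, n_readers, 4),
                dimnames = list(NULL, paste0("reader", seq_len(n_readers)),
                                REGION_LEVELS))
  truth <- matrix(NA_real_, n_subjects, 4, dimnames = list(NULL, REGION_LEVELS))
  cfg <- measure_config()
  for (i in seq_len(n_subjects)) {
    sl <- pmin(24.9, pmax(-19.9, draws$base[i] + region_offsets))
    truth[i, ] <- sl
    spec <- base_spec
    spec$slopes <- sl
    spec$seed <- draws$mesh_seeds[i]
    tib <- generate_tibia(spec)
    axis <- fit_axis(tib$mesh, start_offset = cfg$start_offset,
                     step = cfg$step, area_factor = cfg$area_factor,
                     refine_iterations = cfg$refine_iterations)
    frame <- build_frame(axis, tib$patches)
    measured <- vapply(REGION_LEVELS, function(rg) {
      compute_slope(fit_plane(tib$patches[[rg]]$points), axis, frame,
                    region = rg)$slope_deg
    }, numeric(1))
    for (r in seq_len(n_readers)) {
      if (model == "noise") {
        vals[i, r, ] <- measured + reader_noise_sd * draws$noise[i, r, ]
      } else {
        jittered <- with_seed(draws$jitter_seeds[i, r], {
          vapply(REGION_LEVELS, function(rg) {
            pts <- erode_patch(tib$patches[[rg]]$points,
                               keep_frac = draws$keep_frac[i, r])
            compute_slope(fit_plane(pts), axis, frame, region = rg)$slope_deg
          }, numeric(1))
        })
        vals[i, r, ] <- jittered + reader_noise_sd * draws$noise[i, r, ]
      }
    }
  }
  ratings <- lapply(stats::setNames(seq_along(REGION_LEVELS), REGION_LEVELS),
                    function(j) as_ratings_matrix(vals[, , j]))
  long <- do.call(rbind, lapply(REGION_LEVELS, function(rg) {
    do.call(rbind, lapply(seq_len(n_readers), function(r) {
      tibble::tibble(subject = seq_len(n_subjects),
                     reader = paste0("reader", r), region = rg,
                     slope_deg = vals[, r, rg])
    }))
  }))
  list(ratings = ratings, long = dplyr::as_tibble(long),
       truth = dplyr::bind_cols(tibble::tibble(subject = seq_len(n_subjects)),
                                tibble::as_tibble(truth)))
}

# boundary erosion + random subsampling of a patch: drop the outermost
# (1 - keep_frac)/2 fraction by in-plane radius, then keep a random
# keep_frac of the remainder
erode_patch <- function(points, keep_frac) {
  ctr <- colMeans(points)
  r <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  keep <- r <= stats::quantile(r, 1 - (1 - keep_frac) / 2)
  pts <- points[keep, , drop = FALSE]
  n_keep <- max(10L, floor(nrow(pts) * keep_frac))
  if (n_keep < nrow(pts)) {
    pts <- pts[sample.int(nrow(pts), n_keep), , drop = FALSE]
  }
  pts
}
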