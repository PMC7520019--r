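# a fitted axis for frame construction: flared shaft aligned with +z
flared_axis <- function() {
  fit_axis(generate_shaft(length = 200, radius = 15, flare_radius = 35,
                          flare_length = 40))
}

# four tiny patches with plateau centroids at (+/-25, 0, 200)
centroid_patches <- function(ml_offset = 25, ap = 0) {
  disc <- function(cx) {
    t <- 2 * pi * (0:11) / 12
    cbind(cx + 3 * cos(t), ap + 3 * sin(t), 200)
  }
  list(labeled_patch("medial_plateau", disc(ml_offset)),
       labeled_patch("medial_rim", disc(ml_offset + 5)),
       labeled_patch("lateral_plateau", disc(-ml_offset)),
       labeled_patch("lateral_rim", disc(-ml_offset - 5)))
}

test_that("the frame is orthonormal, right-handed, and medial-directed", {
  ax <- flared_axis()
  fr <- build_frame(ax, centroid_patches())
  expect_lt(angle_deg(fr$mediolateral, c(1, 0, 0)), 1e-9 * 180 / pi)
  expect_lt(abs(sum(fr$mediolateral * fr$longitudinal)), 1e-9)
  expect_lt(abs(sum(fr$mediolateral * fr$anteroposterior)), 1e-9)
  det <- det(cbind(fr$mediolateral, fr$anteroposterior, fr$longitudinal))
  expect_equal(det, 1, tolerance = 1e-9)
  expect_identical(fr$provenance, "derived_from_patches")
})

test_that("a mediolateral override is Gram-Schmidt orthogonalised", {
  ax <- flared_axis()
  v <- c(0.999, 0.01, 0.04)
  fr <- build_frame(ax, centroid_patches(), override_mediolateral = v)
  long <- fr$longitudinal
  expected <- v - sum(v * long) * long
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(abs(sum(fr$mediolateral * expected)), 1, tolerance = 1e-9)
  expect_identical(fr$provenance, "user_supplied")
  expect_error(build_frame(ax, centroid_patches(),
                           override_mediolateral = ax$direction * 2),
               "within 1 degree")
})

test_that("coincident plateau centroids give a degenerate-frame error", {
  ax <- flared_axis()
  expect_error(build_frame(ax, centroid_patches(ml_offset = 0.2)),
               "degenerate frame")
})

test_that("slope angles follow the posterior-positive sagittal convention", {
  ax <- flared_axis()
  fr <- build_frame(ax, centroid_patches())
  set.seed(41)
  mk_plane <- function(normal) {
    fit_plane(plane_points(100, c(0, 0, 200), normal / sqrt(sum(normal^2))))
  }
  # normal parallel to the axis: flat plateau
  expect_equal(compute_slope(mk_plane(c(0, 0, 1)), ax, fr)$slope_deg, 0,
               tolerance = 1e-9)
  # pure sagittal tilt: normal leaning posterior by 10 deg
  th <- 10 * pi / 180
  expect_equal(compute_slope(mk_plane(c(0, -sin(th), cos(th))), ax, fr)$slope_deg,
               10, tolerance = 1e-7)
  # stored normal sign must not matter
  expect_equal(compute_slope(mk_plane(-c(0, -sin(th), cos(th))), ax, fr)$slope_deg,
               10, tolerance = 1e-7)
})

test_that("mixed sagittal and coronal tilt matches the projection oracle", {
  ax <- flared_axis()
  fr <- build_frame(ax, centroid_patches())
  set.seed(42)
  for (i in 1:10) {
    th <- runif(1, -15, 20) * pi / 180
    ph <- runif(1, -10, 10) * pi / 180
    nrm <- as.numeric(rot_x(th) %*% rot_y(ph) %*% c(0, 0, 1))
    got <- compute_slope(fit_plane(plane_points(200, c(5, -3, 200), nrm)),
                         ax, fr)$slope_deg
    # oracle: drop the mediolateral components of normal and axis, take the
    # signed planar angle (posterior positive)
    ns <- nrm - sum(nrm * fr$mediolateral) * fr$mediolateral
    as_ <- fr$longitudinal
    expected <- atan2(-sum(ns * fr$anteroposterior) / sqrt(sum(ns^2)),
                      sum(ns * as_) / sqrt(sum(ns^2))) * 180 / pi
    expect_equal(got, expected, tolerance = 1e-7)
  }
})

test_that("a normal parallel to the mediolateral axis cannot be projected", {
  ax <- flared_axis()
  fr <- build_frame(ax, centroid_patches())
  pl <- fit_plane(plane_points(50, c(0, 0, 200), c(1, 0, 0)))
  expect_error(compute_slope(pl, ax, fr), "degenerate projection")
})

test_that("recomputing the angle from stored plane and frame reproduces it", {
  tib <- generate_tibia(tibia_spec())
  res <- measure_all(tib$mesh, tib$patches)
  for (rg in res$slopes$region) {
    again <- compute_slope(res$planes[[rg]], res$axis, res$frame, rg)
    expect_equal(again$slope_deg,
                 res$slopes$slope_deg[res$slopes$region == rg],
                 tolerance = 1e-9)
    expect_gt(again$slope_deg, -90); expect_lt(again$slope_deg, 90)
  }
})

test_that("the radiographic two-line slope follows its conventions", {
  cortex <- line2d(c(0, 0), c(0, 100), "posterior_cortex")
  flat <- line2d(c(0, 100), c(50, 100), "plateau_tangent")
  expect_equal(measure_2d_slope(cortex, flat), 0)
  # plateau dropping 6 degrees posteriorly
  drop6 <- line2d(c(0, 100), c(0, 100) + 50 * c(cos(-6 * pi / 180),
                                                sin(-6 * pi / 180)),
                  "plateau_tangent")
  expect_equal(measure_2d_slope(cortex, drop6), 6, tolerance = 1e-9)
  # endpoint order and line orientation must not matter
  drop6r <- line2d(drop6$p2, drop6$p1, "plateau_tangent")
  expect_equal(measure_2d_slope(cortex, drop6r), 6, tolerance = 1e-9)
})

test_that("cortex tilt is compensated: 3 and 9 degree tilts give 6", {
  rot2 <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                           sin(a) * p[1] + cos(a) * p[2])
  a3 <- -3 * pi / 180; a9 <- -9 * pi / 180
  cortex <- line2d(rot2(c(0, 0), a3), rot2(c(0, 100), a3), "posterior_cortex")
  plateau <- line2d(rot2(c(0, 0), a9), rot2(c(50, 0), a9), "plateau_tangent")
  expect_equal(measure_2d_slope(cortex, plateau), 6, tolerance = 1e-9)
})

test_that("parallel lines are rejected as physically impossible", {
  cortex <- line2d(c(0, 0), c(0, 100), "posterior_cortex")
  par <- line2d(c(5, 0), c(5, 80), "plateau_tangent")
  expect_error(measure_2d_slope(cortex, par), "parallel")
  expect_error(line2d(c(1, 1), c(1, 1), "posterior_cortex"), "coincide")
})
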