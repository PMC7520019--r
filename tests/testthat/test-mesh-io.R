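test_that("STL and PLY round-trips preserve geometry and merge the triangle soup", {
  cube <- cube_mesh()
  for (fmt in c("stl_ascii", "stl_binary", "ply")) {
    ext <- if (fmt == "ply") ".ply" else ".stl"
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(cube, path, format = fmt)
    m <- read_mesh(path)
    expect_equal(nrow(m$vertices), 8L, info = fmt)
    expect_equal(nrow(m$faces), 12L, info = fmt)
    expect_equal(sort_rows(m$vertices), sort_rows(unname(cube$vertices)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("mesh round-trip preserves face topology exactly for PLY", {
  tib <- generate_tibia(tibia_spec(segments = 16, ring_spacing = 10))
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(tib$mesh, path)
  m <- read_mesh(path)
  expect_equal(m$faces, tib$mesh$faces)
  expect_equal(m$vertices, tib$mesh$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-area faces are dropped with a warning on load", {
  cube <- cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path, format = "stl_ascii")
  lines <- readLines(path)
  degen <- c(" facet normal 0 0 1", "  outer loop",
             "   vertex 0 0 0", "   vertex 0 0 0", "   vertex 1 1 1",
             "  endloop", " endfacet")
  writeLines(append(lines, degen, after = length(lines) - 1L), path)
  expect_warning(m <- read_mesh(path), "1 degenerate")
  expect_equal(nrow(m$faces), 12L)
})

test_that("corrupt and empty mesh files are refused", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines("not a mesh at all", path)
  expect_error(read_mesh(path), "not a valid STL")
  expect_error(read_mesh("no/such/file.stl"), "not found")
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0", "end_header"), ply)
  expect_error(read_mesh(ply), "ASCII PLY")
})

test_that("unit checks refuse anything but millimetres", {
  expect_error(surface_mesh(diag(3), rbind(c(1, 2, 3)), units = "cm"), "mm")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"units": "cm"}', js)
  expect_error(read_patches(js), "units")
})

test_that("index patches resolve against the mesh and conserve counts", {
  tib <- generate_tibia(tibia_spec(segments = 16, ring_spacing = 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_patches(tib$patches, path)
  back <- read_patches(path, tib$mesh)
  for (rg in names(tib$patches)) {
    expect_equal(nrow(back[[rg]]$points), nrow(tib$patches[[rg]]$points))
    expect_equal(back[[rg]]$points, tib$patches[[rg]]$points,
                 ignore_attr = TRUE)
  }
  # resolved points are a subset of mesh vertices
  expect_true(all(back$medial_rim$points %in% tib$mesh$vertices))
  expect_error(read_patches(path), "mesh is required")
})

test_that("explicit-point patches round-trip bit-exactly", {
  set.seed(11)
  pts <- lapply(tibslope:::REGION_LEVELS, function(rg) {
    labeled_patch(rg, matrix(rnorm(30, sd = 20), ncol = 3))
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_patches(pts, path)
  back <- read_patches(path)
  for (i in seq_along(pts)) {
    expect_identical(back[[pts[[i]]$region]]$points, unname(pts[[i]]$points))
  }
})

test_that("patch schema violations are reported by name", {
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"units":"mm",',
                    '"medial_rim":{"points":[[0,0,0],[1,0,0],[0,1,0]]},',
                    '"medial_rim":{"points":[[0,0,0],[1,0,0],[0,1,0]]}}'), js)
  expect_error(read_patches(js), "duplicated region.*medial_rim")
  writeLines('{"units":"mm","medial_rim":{"points":[[0,0,0],[1,0,0],[0,1,0]]}}',
             js)
  expect_error(read_patches(js), "missing region")
  tib <- generate_tibia(tibia_spec(segments = 16, ring_spacing = 10))
  nv <- nrow(tib$mesh$vertices)
  writeLines(jsonlite::toJSON(
    c(list(units = "mm"),
      setNames(rep(list(list(vertex_indices = c(0, 1, nv + 5))), 4),
               tibslope:::REGION_LEVELS)), auto_unbox = TRUE), js)
  expect_error(read_patches(js, tib$mesh), "out of range")
})

test_that("degenerate patches are rejected at construction", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(labeled_patch("medial_rim", line), "collinear")
  expect_error(labeled_patch("medial_rim", line[1:2, ]), "at least 3")
})

test_that("ratings CSV reading enforces the study-table contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  m <- matrix(rnorm(54 * 2, 7.5, 4), 54, 2)
  utils::write.csv(data.frame(subject = sprintf("knee%02d", 1:54),
                              AH = m[, 1], LJ = m[, 2]),
                   path, row.names = FALSE)
  r <- read_ratings(path)
  expect_equal(dim(r), c(54L, 2L))
  expect_equal(colnames(r), c("AH", "LJ"))

  utils::write.csv(data.frame(subject = "k1", AH = 7.1, LJ = 7.3)[0, ],
                   path, row.names = FALSE)
  expect_error(read_ratings(path), "2 subjects")
  utils::write.csv(data.frame(subject = "k1", AH = 7.1, LJ = 7.3),
                   path, row.names = FALSE)
  expect_error(read_ratings(path), "2 subjects")
  utils::write.csv(data.frame(subject = c("k1", "k2"), AH = c(7.1, NA),
                              LJ = c(7.3, 6.9)), path, row.names = FALSE)
  expect_error(read_ratings(path), "k2.*AH")
})

test_that("measurement reports round-trip slope values bit-exactly", {
  tib <- generate_tibia(tibia_spec(segments = 32, ring_spacing = 5))
  res <- measure_all(tib$mesh, tib$patches)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(res, path)
  rep <- read_report(path)
  expect_identical(rep$slopes$slope_deg, res$slopes$slope_deg)
  expect_identical(rep$axis$stop_reason, res$axis$stop_reason)
  expect_equal(unlist(rep$frame$mediolateral), res$frame$mediolateral,
               ignore_attr = TRUE)
})

test_that("digitized line files require the explicit image convention", {
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"lines": []}', js)
  expect_error(read_lines2d(js), "convention")
  writeLines(paste0('{"convention": "x_posterior_y_proximal", "lines": [',
                    '{"role": "posterior_cortex", "p1": [0,0], "p2": [0,100]},',
                    '{"role": "plateau_tangent", "p1": [0,100], "p2": [50,100]}]}'),
             js)
  l <- read_lines2d(js)
  expect_s3_class(l$posterior_cortex, "line2d")
  expect_equal(measure_2d_slope(l$posterior_cortex, l$plateau_tangent), 0)
})
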