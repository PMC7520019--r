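#' Read a triangle mesh from STL or PLY
#'
#' Reads binary STL, ASCII STL, or ASCII PLY. Duplicate vertices are merged
#' within 1e-6 mm and zero-area faces dropped with a warning (STL stores a
#' triangle soup, so merging is what reconstructs shared topology).
#'
#' @param path Path to the mesh file.
#' @param format `"auto"` (default, from extension + content sniffing),
#'   `"stl"`, or `"ply"`.
#' @return A [surface_mesh].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension \".", ext,
                          "\"; pass format=", call. = FALSE))
  }
  raw <- switch(format,
                stl = read_stl(path),
                ply = read_ply(path))
  surface_mesh(raw$vertices, raw$faces, clean = TRUE)
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh A [surface_mesh].
#' @param path Output path.
#' @param format `"auto"` (from extension), `"stl_binary"`, `"stl_ascii"`, or
#'   `"ply"` (ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl_binary", "stl_ascii", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl_binary", ply = "ply",
                     stop("cannot infer mesh format from extension \".", ext,
                          "\"", call. = FALSE))
  }
  switch(format,
         stl_binary = write_stl_binary(mesh, path),
         stl_ascii  = write_stl_ascii(mesh, path),
         ply        = write_ply(mesh, path))
  invisible(path)
}

# STL sniffing: a binary STL is exactly 84 + 50 * ntriangles bytes; ASCII
# starts with "solid". Some binary exporters also start with "solid", so the
# size check wins.
read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    close(con); on.exit()
    return(read_stl_binary(path))
  }
  txt <- rawToChar(header[header != as.raw(0)])
  if (!grepl("^\\s*solid", txt)) {
    stop("not a valid STL file (neither binary size signature nor ",
         "\"solid\" header): ", path, call. = FALSE)
  }
  read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ntri < 1L) stop("empty STL: 0 triangles", call. = FALSE)
  rec <- readBin(con, "raw", 50L * ntri)
  if (length(rec) < 50L * ntri) stop("truncated binary STL: ", path, call. = FALSE)
  m <- matrix(rec, nrow = 50L)
  tri_raw <- as.raw(m[1:48, ])                       # normal + 3 verts, 12 floats
  vals <- readBin(tri_raw, "numeric", n = 12L * ntri, size = 4L,
                  endian = "little")
  vals <- matrix(vals, nrow = 12L)                   # cols = triangles
  verts <- rbind(t(vals[4:6, ]), t(vals[7:9, ]), t(vals[10:12, ]))
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]                # v1,v2,v3 per triangle
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found in ASCII STL: ", path, call. = FALSE)
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
  if (length(nums) %% 9L != 0L) {
    stop("corrupt ASCII STL (vertex count not a multiple of 3): ", path,
         call. = FALSE)
  }
  verts <- matrix(nums, ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  ntri <- nrow(f)
  n <- face_normals(v, f)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "tibslope binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  block <- rbind(t(n), t(v[f[, 1], , drop = FALSE]), t(v[f[, 2], , drop = FALSE]),
                 t(v[f[, 3], , drop = FALSE]))          # 12 x ntri
  fl <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  fl <- matrix(fl, ncol = ntri)                          # 48 bytes per tri
  out <- rbind(fl, matrix(as.raw(0L), nrow = 2L, ncol = ntri))
  writeBin(as.raw(out), con)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(v, f)
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c("solid tibslope",
             as.vector(rbind(
               sprintf(" facet normal %s", fmt(n)),
               "  outer loop",
               sprintf("   vertex %s", fmt(v[f[, 1], , drop = FALSE])),
               sprintf("   vertex %s", fmt(v[f[, 2], , drop = FALSE])),
               sprintf("   vertex %s", fmt(v[f[, 3], , drop = FALSE])),
               "  endloop",
               " endfacet")),
             "endsolid tibslope")
  writeLines(lines, path)
}

face_normals <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

read_ply <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(trimws(magic), "ply")) {
    stop("not a PLY file: ", path, call. = FALSE)
  }
  nvert <- NA_integer_; nface <- NA_integer_
  vprops <- character(0)
  in_vertex <- FALSE
  repeat {
    ln <- trimws(readLines(con, 1L))
    if (!length(ln)) stop("truncated PLY header: ", path, call. = FALSE)
    tk <- strsplit(ln, "\\s+")[[1]]
    if (tk[1] == "format") {
      if (tk[2] != "ascii") {
        stop("only ASCII PLY is supported, got format \"", tk[2], "\"",
             call. = FALSE)
      }
    } else if (tk[1] == "element") {
      in_vertex <- tk[2] == "vertex"
      if (tk[2] == "vertex") nvert <- as.integer(tk[3])
      if (tk[2] == "face") nface <- as.integer(tk[3])
    } else if (tk[1] == "property" && in_vertex && tk[2] != "list") {
      vprops <- c(vprops, tk[3])
    } else if (tk[1] == "end_header") break
  }
  if (is.na(nvert) || is.na(nface)) {
    stop("PLY header missing vertex or face element: ", path, call. = FALSE)
  }
  body <- readLines(con)
  body <- body[nzchar(trimws(body))]
  if (length(body) < nvert + nface) stop("truncated PLY body: ", path, call. = FALSE)
  vv <- scan(text = body[seq_len(nvert)], quiet = TRUE)
  vv <- matrix(vv, nrow = nvert, byrow = TRUE)
  ixyz <- match(c("x", "y", "z"), vprops)
  if (any(is.na(ixyz))) stop("PLY vertex element lacks x/y/z", call. = FALSE)
  verts <- vv[, ixyz, drop = FALSE]
  fl <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
  faces <- t(vapply(fl, function(tk) {
    cnt <- as.integer(tk[1])
    if (cnt != 3L) stop("non-triangular PLY face (", cnt, " vertices); ",
                        "triangulate the mesh first", call. = FALSE)
    as.integer(tk[2:4]) + 1L
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  lines <- c("ply", "format ascii 1.0",
             "comment tibslope, units mm",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header",
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
}

#' Read articular patch labels from JSON
#'
#' The schema is a JSON object with a required `"units": "mm"` field and one
#' entry per region (`medial_plateau`, `medial_rim`, `lateral_plateau`,
#' `lateral_rim`), each either `{"vertex_indices": [...]}` (0-based, resolved
#' against `mesh`) or `{"points": [[x,y,z], ...]}`.
#'
#' @param path Path to the patch JSON.
#' @param mesh A [surface_mesh]; required when any region uses vertex indices.
#' @return Named list of four [labeled_patch] objects.
#' @export
read_patches <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("patch file not found: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(readChar(path, file.info(path)$size),
                           simplifyVector = FALSE)
  nm <- names(js)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicated region in patch file: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  units <- js[["units"]]
  if (is.null(units) || !identical(units, "mm")) {
    stop("patch file must declare \"units\": \"mm\"", call. = FALSE)
  }
  regions <- intersect(nm, REGION_LEVELS)
  missing <- setdiff(REGION_LEVELS, regions)
  if (length(missing)) {
    stop("missing region: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  patches <- lapply(regions, function(rg) {
    entry <- js[[rg]]
    if (!is.null(entry$vertex_indices)) {
      if (is.null(mesh)) {
        stop("region \"", rg, "\" uses vertex indices; a mesh is required",
             call. = FALSE)
      }
      idx0 <- as.integer(unlist(entry$vertex_indices))
      if (any(idx0 < 0L) || any(idx0 >= nrow(mesh$vertices))) {
        stop("region \"", rg, "\": vertex index out of range [0, ",
             nrow(mesh$vertices) - 1L, "]", call. = FALSE)
      }
      labeled_patch(rg, mesh$vertices[idx0 + 1L, , drop = FALSE],
                    vertex_indices = idx0 + 1L)
    } else if (!is.null(entry$points)) {
      pts <- do.call(rbind, lapply(entry$points, as.numeric))
      labeled_patch(rg, pts)
    } else {
      stop("region \"", rg, "\" has neither vertex_indices nor points",
           call. = FALSE)
    }
  })
  as_patch_set(patches)
}

#' Write articular patches to JSON
#'
#' Index-backed patches are written as 0-based `vertex_indices`; explicit
#' patches as `points`.
#'
#' @param patches List of [labeled_patch].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patches <- function(patches, path) {
  patches <- as_patch_set(patches)
  out <- list(units = "mm")
  for (p in patches) {
    out[[p$region]] <- if (!is.null(p$vertex_indices)) {
      list(vertex_indices = as.integer(p$vertex_indices - 1L))
    } else {
      list(points = unname(p$points))
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a subjects-by-readers ratings matrix from CSV
#'
#' Expects a header row of reader IDs and one row per subject. A first column
#' named `subject` (case-insensitive) provides subject IDs; otherwise rows are
#' numbered. No missing cells are allowed; at least 2 subjects and 2 readers.
#'
#' @param path Path to the CSV.
#' @return A numeric matrix (class `ratings_matrix`) with subject rownames and
#'   reader colnames.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(df)[1]) %in% c("subject", "id", "knee")) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    rn <- as.character(seq_len(nrow(df)))
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  as_ratings_matrix(m)
}

#' Validate a ratings matrix
#'
#' @param m Numeric matrix, subjects in rows, readers in columns.
#' @return The matrix with class `ratings_matrix`.
#' @export
as_ratings_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("at least 2 subjects required, got ", nrow(m), call. = FALSE)
  if (ncol(m) < 2L) stop("at least 2 readers required, got ", ncol(m), call. = FALSE)
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing rating for subject \"",
         if (is.null(rownames(m))) w[1] else rownames(m)[w[1]],
         "\", reader \"",
         if (is.null(colnames(m))) w[2] else colnames(m)[w[2]],
         "\"", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("reader", seq_len(ncol(m)))
  class(m) <- c("ratings_matrix", "matrix", "array")
  m
}

#' Write a measurement report to JSON
#'
#' Serialises a [measure_all()] result: per-region slopes and plane
#' parameters, axis diagnostics, frame vectors with provenance, the
#' configuration used, the package version and input file hashes, so a
#' measurement can be audited and re-derived.
#'
#' @param result A `slope_measurement` from [measure_all()].
#' @param path Output JSON path.
#' @param inputs Optional named character vector of input file paths; MD5
#'   hashes are recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, inputs = NULL) {
  stopifnot(inherits(result, "slope_measurement"))
  ax <- result$axis
  rep <- list(
    software = list(package = "tibslope",
                    version = as.character(utils::packageVersion("tibslope"))),
    units = "mm",
    config = result$config,
    slopes = lapply(seq_len(nrow(result$slopes)), function(i) {
      r <- result$slopes[i, ]
      pl <- result$planes[[r$region]]
      list(region = r$region, slope_deg = r$slope_deg,
           plane = list(centroid = pl$centroid, normal = pl$normal,
                        rms_residual = pl$rms_residual, n_points = pl$n_points))
    }),
    frame = list(origin = result$frame$origin,
                 longitudinal = result$frame$longitudinal,
                 mediolateral = result$frame$mediolateral,
                 anteroposterior = result$frame$anteroposterior,
                 provenance = result$frame$provenance),
    axis = list(point = ax$point, direction = ax$direction,
                rms_centroid_residual = ax$rms_centroid_residual,
                first_section_area = ax$first_section_area,
                stop_reason = ax$stop_reason,
                stations = lapply(ax$cross_sections, function(cs) {
                  list(station_offset = cs$station_offset, area = cs$area,
                       centroid = cs$centroid)
                }))
  )
  if (!is.null(inputs)) {
    rep$input_md5 <- as.list(tools::md5sum(inputs))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a measurement report written by [write_report()]
#'
#' @param path Report JSON path.
#' @return The parsed report as a list; `$slopes` is a tibble.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(readChar(path, file.info(path)$size),
                            simplifyVector = FALSE)
  rep$slopes <- dplyr::bind_rows(lapply(rep$slopes, function(s) {
    tibble::tibble(region = s$region, slope_deg = s$slope_deg)
  }))
  rep
}

#' Read digitized radiograph lines from JSON
#'
#' The file must carry an explicit coordinate-convention tag
#' `"convention": "x_posterior_y_proximal"` (x grows anterior to posterior,
#' y grows distal to proximal) and two lines with roles `posterior_cortex`
#' and `plateau_tangent`, each `{"role": ..., "p1": [x, y], "p2": [x, y]}`.
#'
#' @param path Path to the lines JSON.
#' @return Named list of two [line2d] objects.
#' @export
read_lines2d <- function(path) {
  if (!file.exists(path)) stop("lines file not found: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(readChar(path, file.info(path)$size),
                           simplifyVector = FALSE)
  if (!identical(js$convention, "x_posterior_y_proximal")) {
    stop("lines file must declare \"convention\": \"x_posterior_y_proximal\"",
         call. = FALSE)
  }
  lines <- lapply(js$lines, function(l) {
    line2d(unlist(l$p1), unlist(l$p2), role = l$role)
  })
  roles <- vapply(lines, function(l) l$role, character(1))
  need <- c("posterior_cortex", "plateau_tangent")
  if (!setequal(roles, need)) {
    stop("lines file must contain exactly roles ",
         paste(need, collapse = " and "), call. = FALSE)
  }
  stats::setNames(lines, roles)
}
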