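# File formats: STL (ASCII and binary little-endian), PLY (ASCII), landmark
# and result JSON. STL stores float32, so round-trips through STL lose
# precision beyond ~1e-7 relative; PLY is written with full double precision
# and is the recommended format for lossless round-trips.

#' Read a triangle mesh from STL or PLY
#'
#' Duplicate vertices are merged by exact coordinate match and zero-area
#' faces dropped. The format is chosen by file extension, with content
#' sniffing for the STL dialect (ASCII vs binary).
#'
#' @param path file path (`.stl` or `.ply`).
#' @return A [trimesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    fna_stop("fna_io", "mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply(path))
  if (ext != "stl")
    fna_stop("fna_io", "unsupported mesh format '.%s' (use STL or PLY)", ext)
  # sniff dialect: ASCII STL starts with "solid" AND contains "facet"
  head_raw <- readBin(path, "raw", n = 512)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  Encoding(head_txt) <- "bytes"
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  mesh_from_triangle_soup(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    fna_stop("fna_io", "malformed ASCII STL: %d vertex lines", length(vl))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  m <- do.call(rbind, nums)
  if (anyNA(m)) fna_stop("fna_io", "non-numeric vertex in ASCII STL")
  m
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  if (sz < 84) fna_stop("fna_io", "truncated binary STL: only %d bytes", sz)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + ntri * 50
  if (sz < expected)
    fna_stop("fna_io",
             "truncated binary STL: %d triangles declared need %d bytes, file has %d (missing from offset %d)",
             ntri, expected, sz, sz)
  rec <- readBin(con, "raw", n = ntri * 50)
  rec <- matrix(rec, nrow = 50)
  flo <- readBin(as.vector(rec[1:48, ]), "double", size = 4, n = 12 * ntri,
                 endian = "little")
  flo <- matrix(flo, nrow = 12)  # nx ny nz v1 v2 v3 per column
  t(matrix(flo[4:12, ], nrow = 3))
}

mesh_from_triangle_soup <- function(v) {
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- v[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  n0 <- nrow(faces)
  mesh <- trimesh(verts, faces)
  dropped <- n0 - nrow(mesh$faces)
  if (dropped > 0)
    message(sprintf("read_mesh: dropped %d zero-area face(s)", dropped))
  mesh
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [trimesh()].
#' @param path output path; extension selects the format.
#' @param binary for STL: write the binary dialect (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(write_ply(mesh, path))
  if (ext != "stl")
    fna_stop("fna_io", "unsupported mesh format '.%s' (use STL or PLY)", ext)
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
    pay <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    pay <- matrix(pay, nrow = 48)
    out <- rbind(pay, matrix(as.raw(0), 2, ncol(pay)))
    writeBin(as.vector(out), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid fnaxis", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid fnaxis", con)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    fna_stop("fna_io", "not a PLY file: %s", path)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) fna_stop("fna_io", "PLY header has no end_header")
  header <- trimws(lines[seq_len(hend)])
  if (!any(grepl("^format ascii", header)))
    fna_stop("fna_io", "only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    fna_stop("fna_io", "PLY header missing vertex/face counts")
  body <- lines[(hend + 1L):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    n <- as.integer(p[1])
    if (n != 3L) fna_stop("fna_io", "non-triangular PLY face (%d vertices)", n)
    as.integer(p[2:4]) + 1L
  }))
  trimesh(verts, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment fnaxis",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a landmark file (JSON)
#'
#' Expects keys `gt_tip`, `lt_tip`, `it_mid`, `head_hint`, each an `[x, y, z]`
#' triple in mm; optional `schema_version` and `metadata`. Collinear
#' landmark triplets are rejected at load time.
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) fna_stop("fna_io", "landmark file not found: %s", path)
  obj <- jsonlite::fromJSON(path)
  need <- c("gt_tip", "lt_tip", "it_mid", "head_hint")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    fna_stop("fna_io", "landmark file missing key(s): %s",
             paste(miss, collapse = ", "))
  landmark_set(obj$gt_tip, obj$lt_tip, obj$it_mid, obj$head_hint)
}

#' Write a landmark file (JSON)
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @param metadata optional named list stored verbatim.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, metadata = NULL) {
  obj <- list(schema_version = 1L,
              gt_tip = lm$gt_tip, lt_tip = lm$lt_tip,
              it_mid = lm$it_mid, head_hint = lm$head_hint)
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param fit an `fna_fit` from [fit_fna()] or [iterate_axis()].
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_fit_result <- function(fit, path = NULL) {
  obj <- list(
    tool = "fnaxis",
    version = tryCatch(as.character(utils::packageVersion("fnaxis")),
                       error = function(e) "unknown"),
    fna = list(point = fit$fna$point, direction = fit$fna$direction),
    cylinder = list(radius = fit$cylinder$radius,
                    rms_residual = fit$cylinder$rms_residual,
                    degenerate = fit$cylinder$degenerate),
    per_iteration_axes = lapply(fit$per_iteration_axes, function(a)
      list(point = a$point, direction = a$direction)),
    config = unclass(fit$config)
  )
  if (!is.null(fit$head_sphere)) {
    obj$head_sphere <- list(centre = fit$head_sphere$centre,
                            radius = fit$head_sphere$radius)
    obj$dbhf <- fit$dbhf
  }
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline from files
#'
#' Reads a mesh and a landmark file, fits the femoral neck axis, and
#' optionally writes the JSON report and a per-section contour dump.
#'
#' @param mesh_path STL/PLY mesh path.
#' @param landmarks_path landmark JSON path.
#' @param cfg a [section_config()].
#' @param out optional path for the JSON report.
#' @param contour_dump optional CSV path: final-iteration contour points
#'   (`section`, `x`, `y`, `z`).
#' @return The `fna_fit`, invisibly.
#' @export
run_fit <- function(mesh_path, landmarks_path, cfg = section_config(),
                    out = NULL, contour_dump = NULL) {
  mesh <- read_mesh(mesh_path)
  lm <- read_landmarks(landmarks_path)
  fit <- fit_fna(mesh, lm, cfg)
  if (!is.null(out)) write_fit_result(fit, out)
  if (!is.null(contour_dump)) {
    dump <- do.call(rbind, lapply(seq_along(fit$last_contours), function(i) {
      lp <- fit$last_contours[[i]]$loop
      data.frame(section = i, x = lp[, 1], y = lp[, 2], z = lp[, 3])
    }))
    utils::write.csv(dump, contour_dump, row.names = FALSE)
  }
  invisible(fit)
}
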