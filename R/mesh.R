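# Triangle-mesh container and validation. A mesh is a list with `vertices`
# (n x 3 numeric, mm) and `faces` (m x 3 integer, 1-based). The slicing code
# requires watertight (closed 2-manifold) input: every undirected edge must be
# shared by exactly two faces.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param validate if `TRUE` (default), check index ranges and drop
#'   zero-area faces.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) fna_stop("fna_bad_mesh", "vertices must be n x 3")
  if (ncol(faces) != 3L) fna_stop("fna_bad_mesh", "faces must be m x 3")
  if (validate) {
    if (nrow(faces) == 0L || nrow(vertices) < 3L)
      fna_stop("fna_bad_mesh", "mesh is empty")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      fna_stop("fna_bad_mesh", "face indices out of range")
    # drop only topologically degenerate faces (repeated vertex index or
    # exactly zero area); tiny-but-positive slivers are kept so that closed
    # meshes stay closed
    a <- face_areas(vertices, faces)
    bad <- a == 0 | faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(bad)) faces <- faces[!bad, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

face_areas <- function(v, f) {
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a mesh is watertight
#'
#' A mesh is watertight (closed) when every undirected edge is shared by
#' exactly two faces. Non-watertight meshes cannot be sliced into closed
#' contours and are rejected rather than repaired.
#'
#' @param mesh a [trimesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Require a watertight mesh, raising a classed error otherwise
#' @noRd
assert_watertight <- function(mesh) {
  if (!is_watertight(mesh))
    fna_stop("fna_not_watertight",
             "mesh is not watertight (some edges are not shared by exactly two faces); repair upstream")
  invisible(mesh)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [trimesh()].
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive when face
#' windings point outward.
#' @param mesh a [trimesh()].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [trimesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return The transformed [trimesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, as_p3(translation), "+")
  trimesh(v, mesh$faces, validate = FALSE)
}

#' Apply a rigid transform to a point, line, or landmark set
#' @noRd
transform_point <- function(p, rotation, translation) {
  drop(rotation %*% as_p3(p)) + as_p3(translation)
}

#' @noRd
transform_line <- function(l, rotation, translation) {
  line3(transform_point(l$point, rotation, translation),
        drop(rotation %*% l$direction))
}
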