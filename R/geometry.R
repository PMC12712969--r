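# Geometric primitives used throughout the package. All lengths are in
# millimetres; directions are unit vectors. Degeneracy tolerances below guard
# numerical validity and are deliberately not user-configurable.

.TOL_UNIT <- 1e-9     # unit-norm tolerance for directions/normals
.TOL_AREA <- 1e-6     # mm^2, minimum triangle area for a landmark plane
.TOL_POLY_AREA <- 1e-9  # mm^2, minimum polygon area for a centroid

#' Signal a classed error
#'
#' All errors raised by the package carry a subclass so callers (and the
#' command-line wrapper) can map failure modes to exit codes.
#' @noRd
fna_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fnaxis_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Coerce to a 3-vector
#' @noRd
as_p3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    fna_stop("fna_invalid_point", "expected a finite 3-vector, got [%s]",
             paste(format(p), collapse = ", "))
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .TOL_UNIT)
    fna_stop("fna_zero_vector", "cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a plane from an origin point and a normal vector
#'
#' @param origin numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3; normalized internally.
#' @return An object of class `plane3` with fields `origin` and unit `normal`.
#' @export
plane3 <- function(origin, normal) {
  structure(list(origin = as_p3(origin), normal = unitize(as_p3(normal))),
            class = "plane3")
}

#' Construct a 3D line from a point and a direction
#'
#' @param point numeric length-3, a point on the line (mm).
#' @param direction numeric length-3; normalized internally.
#' @return An object of class `line3` with fields `point` and unit `direction`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = as_p3(point), direction = unitize(as_p3(direction))),
            class = "line3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> origin (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' @export
print.line3 <- function(x, ...) {
  cat(sprintf("<line3> point (%.3f, %.3f, %.3f)  direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Plane through three points
#'
#' The normal follows the right-hand rule on the argument order
#' (`cross(p2 - p1, p3 - p1)`); orienting the normal toward the femoral head
#' is the pipeline's job, not this primitive's. The plane origin is the
#' centroid of the three points.
#'
#' @param p1,p2,p3 numeric length-3 points (mm).
#' @return A [plane3()].
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- as_p3(p1); p2 <- as_p3(p2); p3 <- as_p3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) / 2 <= .TOL_AREA)
    fna_stop("fna_degenerate_landmarks",
             "the three points are coincident or collinear (triangle area <= %g mm^2)",
             .TOL_AREA)
  plane3((p1 + p2 + p3) / 3, n)
}

#' Signed distance of points from a plane
#'
#' @param p a length-3 point or an n x 3 matrix of points.
#' @param plane a [plane3()].
#' @return Signed distance(s) in mm, positive on the `+normal` side.
#' @export
plane_signed_distance <- function(p, plane) {
  if (is.matrix(p)) {
    drop((p - matrix(plane$origin, nrow(p), 3, byrow = TRUE)) %*% plane$normal)
  } else {
    sum((as_p3(p) - plane$origin) * plane$normal)
  }
}

#' Orthonormal in-plane chart of a plane
#'
#' Returns two unit vectors `e1`, `e2` spanning the plane so that
#' `(e1, e2, normal)` is right-handed. Used to map contours to 2D and back.
#' @noRd
plane_basis <- function(plane) {
  n <- plane$normal
  a <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- unitize(cross3(a, n))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Area-weighted (lamina) centroid of a simple polygon
#'
#' Shoelace formulas: `A = (1/2) sum(x_i y_{i+1} - x_{i+1} y_i)`,
#' `Cx = (1/(6A)) sum((x_i + x_{i+1})(x_i y_{i+1} - x_{i+1} y_i))` and
#' likewise `Cy`. The result is independent of vertex ordering direction and
#' of the starting vertex.
#'
#' @param poly an n x 2 matrix of vertices (mm), first vertex not repeated.
#' @return Length-2 centroid, with attributes `area` (absolute, mm^2) and
#'   `signed_area`.
#' @export
polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    fna_stop("fna_degenerate_contour", "polygon needs >= 3 two-column vertices")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  w <- x * yn - xn * y
  a <- sum(w) / 2
  if (abs(a) <= .TOL_POLY_AREA)
    fna_stop("fna_degenerate_contour",
             "polygon area %.3g mm^2 below tolerance %g", abs(a), .TOL_POLY_AREA)
  ctr <- c(sum((x + xn) * w), sum((y + yn) * w)) / (6 * a)
  structure(ctr, area = abs(a), signed_area = a)
}

#' Perpendicular distance from point(s) to a line
#'
#' @param p a length-3 point or an n x 3 matrix.
#' @param l a [line3()].
#' @return Distance(s) in mm, `>= 0`.
#' @export
point_line_distance <- function(p, l) {
  d <- l$direction
  if (is.matrix(p)) {
    q <- p - matrix(l$point, nrow(p), 3, byrow = TRUE)
    t <- drop(q %*% d)
    sqrt(pmax(rowSums(q * q) - t^2, 0))
  } else {
    q <- as_p3(p) - l$point
    vnorm(q - sum(q * d) * d)
  }
}

#' Axial coordinate of point(s) along a line
#'
#' Projection parameter `t` such that the closest point on the line is
#' `point + t * direction`.
#' @noRd
line_axial_coord <- function(p, l) {
  if (is.matrix(p)) {
    drop((p - matrix(l$point, nrow(p), 3, byrow = TRUE)) %*% l$direction)
  } else {
    sum((as_p3(p) - l$point) * l$direction)
  }
}

#' Acute angle between two lines, in degrees
#'
#' Symmetric in its arguments and invariant to direction sign flips; always
#' in `[0, 90]` degrees.
#'
#' @param l1,l2 [line3()] objects (plain unit 3-vectors are also accepted).
#' @return Angle in degrees.
#' @export
angle_between_lines <- function(l1, l2) {
  d1 <- if (inherits(l1, "line3")) l1$direction else unitize(as_p3(l1))
  d2 <- if (inherits(l2, "line3")) l2$direction else unitize(as_p3(l2))
  acos(min(1, abs(sum(d1 * d2)))) * 180 / pi
}

#' Rotate a vector about a unit axis (Rodrigues' formula)
#' @noRd
rotate_about_axis <- function(v, axis, angle_deg) {
  k <- unitize(as_p3(axis))
  th <- angle_deg * pi / 180
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

#' Random rotation matrix (Haar-uniform via QR)
#' @noRd
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
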