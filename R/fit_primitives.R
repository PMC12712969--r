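# Least-squares geometric fits: total-least-squares 3D line, algebraic
# sphere, and nonlinear (orthogonal-distance) cylinder.

#' Total-least-squares line through a 3D point cloud
#'
#' The line passes through the cloud mean along the leading principal
#' direction of the centered coordinates, minimizing the sum of squared
#' perpendicular distances over all lines.
#'
#' @param points n x 3 matrix (mm), `n >= 2`, not all coincident.
#' @param orient optional length-3 hint; the returned direction is flipped to
#'   have a positive dot product with it.
#' @return A [line3()] with attribute `residual` (sum of squared orthogonal
#'   distances, mm^2).
#' @export
fit_line_tls <- function(points, orient = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    fna_stop("fna_underdetermined", "need at least 2 points for a line fit")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  if (max(abs(x)) < 1e-12)
    fna_stop("fna_underdetermined", "all points coincide; line undefined")
  sv <- svd(x, nu = 0, nv = 3)
  if (sv$d[1] - sv$d[2] < 1e-9 * max(sv$d[1], 1))
    fna_stop("fna_ambiguous_direction",
             "leading principal values tie (isotropic cloud); direction ambiguous")
  d <- sv$v[, 1]
  if (!is.null(orient)) {
    h <- as_p3(orient)
    if (sum(d * h) < 0) d <- -d
  }
  l <- line3(ctr, d)
  attr(l, "residual") <- sum(sv$d[-1]^2)
  l
}

#' Algebraic least-squares sphere fit
#'
#' Linear least squares on `|p|^2 = 2 c . p + (r^2 - |c|^2)`; exact on
#' noiseless spherical samples, including partial (cap) coverage.
#'
#' @param points n x 3 matrix (mm), `n >= 4`, not coplanar.
#' @return A list of class `sphere3` with `centre` (mm) and `radius` (mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L)
    fna_stop("fna_underdetermined", "need at least 4 points for a sphere fit")
  a <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_ <- qr(a)
  if (qr_$rank < 4L)
    fna_stop("fna_singular_sphere",
             "points are coplanar or otherwise degenerate; sphere fit singular")
  beta <- qr.coef(qr_, b)
  centre <- beta[1:3]
  r2 <- beta[4] + sum(centre^2)
  if (!is.finite(r2) || r2 <= 0)
    fna_stop("fna_singular_sphere", "sphere fit produced non-positive radius")
  structure(list(centre = unname(centre), radius = sqrt(r2)), class = "sphere3")
}

#' @export
print.sphere3 <- function(x, ...) {
  cat(sprintf("<sphere3> centre (%.3f, %.3f, %.3f)  radius %.3f mm\n",
              x$centre[1], x$centre[2], x$centre[3], x$radius))
  invisible(x)
}

#' Orthogonal-distance cylinder fit
#'
#' Levenberg-Marquardt least squares over five parameters (two for the axis
#' point in the plane perpendicular to the initial direction, two for the
#' direction, one for the radius), minimizing `sum((dist_i - r)^2)` where
#' `dist_i` is the radial distance of point i from the axis. Initialized at
#' `init` with radius equal to the mean radial distance.
#'
#' Centroid clouds from an accurately fitted neck axis are nearly collinear,
#' which leaves the radius unidentifiable; when the RMS radial distance about
#' the TLS line is below `collinear_tol` the optimization is skipped and the
#' axis is the TLS line itself with `r = max(RMS, 1e-6)` (flagged by the
#' `degenerate` field).
#'
#' @param points n x 3 matrix (mm), `n >= 6`.
#' @param init a [line3()] initial axis.
#' @param collinear_tol RMS radial distance (mm) below which the collinear
#'   fallback is used. Default 0.1 mm.
#' @return A list of class `cylinder3` with `axis` ([line3()]), `radius`
#'   (mm), `rms_residual` (mm) and logical `degenerate`.
#' @export
fit_cylinder <- function(points, init, collinear_tol = 0.1) {
  points <- as.matrix(points)
  if (nrow(points) < 6L)
    fna_stop("fna_underdetermined", "need at least 6 points for a cylinder fit")
  tls <- fit_line_tls(points, orient = init$direction)
  rms0 <- sqrt(mean(point_line_distance(points, tls)^2))
  if (rms0 < collinear_tol) {
    return(structure(list(axis = tls, radius = max(rms0, 1e-6),
                          rms_residual = rms0, degenerate = TRUE),
                     class = "cylinder3"))
  }
  d0 <- init$direction
  b <- plane_basis(plane3(init$point, d0))
  ctr <- colMeans(points)
  p0 <- init$point + sum((ctr - init$point) * d0) * d0  # axis point near cloud
  r0 <- mean(point_line_distance(points, init))

  resid_fun <- function(par) {
    d <- unitize(d0 + par[3] * b$e1 + par[4] * b$e2)
    p <- p0 + par[1] * b$e1 + par[2] * b$e2
    point_line_distance(points, line3(p, d)) - par[5]
  }
  fit <- minpack.lm::nls.lm(
    par = c(0, 0, 0, 0, r0), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info %in% c(0, 5, 9))
    fna_stop("fna_fit_failure",
             "cylinder optimization did not converge (last RMS residual %.4g mm)",
             sqrt(mean(fit$fvec^2)))
  par <- fit$par
  d <- unitize(d0 + par[3] * b$e1 + par[4] * b$e2)
  if (sum(d * d0) < 0) d <- -d
  axis <- line3(p0 + par[1] * b$e1 + par[2] * b$e2, d)
  structure(list(axis = axis, radius = abs(par[5]),
                 rms_residual = sqrt(mean(fit$fvec^2)), degenerate = FALSE),
            class = "cylinder3")
}

#' @export
print.cylinder3 <- function(x, ...) {
  cat(sprintf("<cylinder3> radius %.3f mm, RMS residual %.4f mm%s\n",
              x$radius, x$rms_residual,
              if (x$degenerate) " (collinear fallback)" else ""))
  print(x$axis)
  invisible(x)
}
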