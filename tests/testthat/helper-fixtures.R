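# Shared fixtures and independent oracles, all built in code.

# Memoize expensive fixtures within a test-file run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Synthetic femur fixtures at a resolution that keeps unit tests fast;
# end-to-end accuracy checks use finer grids.
fixture_femur <- function(pitch = 1.5, ...) {
  args <- list(voxel_pitch = pitch, ...)
  key <- paste0("femur_", paste(deparse(args), collapse = ""))
  cached(key, generate_femur(do.call(femur_spec, args)))
}

# Axis-aligned unit cube trimesh (12 faces), optionally translated/scaled.
cube_mesh <- function(origin = c(0, 0, 0), size = 1) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * size
  v <- sweep(v, 2, origin, "+")
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),  # x = 0
    c(2, 4, 8), c(2, 8, 6),  # x = 1
    c(1, 6, 5), c(1, 2, 6),  # y = 0
    c(3, 8, 4), c(3, 7, 8),  # y = 1
    c(1, 4, 2), c(1, 3, 4),  # z = 0
    c(5, 8, 7), c(5, 6, 8)   # z = 1
  )
  trimesh(v, f)
}

# Sphere mesh via the package isosurfacer (radius r at centre c0).
sphere_mesh <- function(r = 10, c0 = c(0, 0, 0), pitch = 0.5) {
  key <- sprintf("sphere_%g_%g_%g_%g_%g", r, c0[1], c0[2], c0[3], pitch)
  cached(key, {
    xs <- seq(c0[1] - r - 3, c0[1] + r + 3, by = pitch)
    ys <- seq(c0[2] - r - 3, c0[2] + r + 3, by = pitch)
    zs <- seq(c0[3] - r - 3, c0[3] + r + 3, by = pitch)
    g <- as.matrix(expand.grid(xs, ys, zs))
    f <- sqrt(rowSums(sweep(g, 2, c0)^2)) - r
    marching_tetrahedra(array(f, c(length(xs), length(ys), length(zs))),
                        xs, ys, zs)
  })
}

# Cylinder mesh along +z through the origin (finite, capped).
cylinder_mesh <- function(r = 15, zlim = c(-5, 30), pitch = 0.8) {
  key <- sprintf("cyl_%g_%g_%g_%g", r, zlim[1], zlim[2], pitch)
  cached(key, {
    xs <- seq(-r - 3, r + 3, by = pitch)
    zs <- seq(zlim[1] - 3, zlim[2] + 3, by = pitch)
    g <- as.matrix(expand.grid(xs, xs, zs))
    f <- pmax(sqrt(g[, 1]^2 + g[, 2]^2) - r, zlim[1] - g[, 3], g[, 3] - zlim[2])
    marching_tetrahedra(array(f, c(length(xs), length(xs), length(zs))),
                        xs, xs, zs)
  })
}

# Simple random polygon: perturbed star-convex vertices around the origin.
random_polygon <- function(n = 8, scale = 1) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.3, 1) * scale
  cbind(r * cos(th), r * sin(th))
}

# Rasterization oracle for the polygon centroid: area-weighted mean of the
# midpoints of grid pixels inside the polygon (even-odd rule).
raster_centroid <- function(poly, h = 1e-3) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- seq(xr[1] + h / 2, xr[2], by = h)
  ys <- seq(yr[1] + h / 2, yr[2], by = h)
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  c(mean(px[inside]), mean(py[inside]))
}

# Brute-force 1-D minimization oracle for point-to-line distance.
min_dist_oracle <- function(p, l) {
  f <- function(t) sqrt(sum((p - (l$point + t * l$direction))^2))
  stats::optimize(f, interval = c(-1e3, 1e3), tol = 1e-12)$objective
}

# Brute-force random-candidate oracle for the TLS line: returns the lowest
# residual among M random (point, direction) candidates.
brute_line_residual <- function(pts, M = 1e5) {
  dirs <- matrix(stats::rnorm(3 * M), M, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ctr <- colMeans(pts)
  offs <- matrix(stats::rnorm(3 * M, sd = 1), M, 3) +
    matrix(ctr, M, 3, byrow = TRUE)
  A <- dirs %*% t(pts)        # candidate-dot-points
  pd <- rowSums(dirs * offs)
  B <- offs %*% t(pts)
  p2 <- rowSums(offs^2)
  x2 <- rowSums(pts^2)
  n <- nrow(pts)
  rr <- matrix(x2, M, n, byrow = TRUE) - 2 * B + p2 - (A - pd)^2
  min(rowSums(rr))
}

# Longhand ICC(2,1) from explicit sums of squares (independent of icc()).
longhand_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Longhand balanced two-way ANOVA from cell means (independent of car/lm).
longhand_anova_balanced <- function(df) {
  a <- factor(df$gender); b <- factor(df$side); y <- df$value
  grand <- mean(y)
  na <- nlevels(a); nb <- nlevels(b)
  r <- length(y) / (na * nb)  # per-cell n, balanced
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  cm <- tapply(y, interaction(a, b), mean)
  ss_a <- r * nb * sum((am - grand)^2)
  ss_b <- r * na * sum((bm - grand)^2)
  cell_of <- interaction(a, b)
  ss_ab <- r * sum((cm - rep(am, times = nb) - rep(bm, each = na) + grand)^2)
  ss_err <- sum((y - cm[cell_of])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_err = ss_err,
       ss_tot = sum((y - grand)^2))
}

# Rigid-transform helpers for equivariance tests.
apply_rigid_lm <- function(lm, R, tv) {
  landmark_set(drop(R %*% lm$gt_tip) + tv, drop(R %*% lm$lt_tip) + tv,
               drop(R %*% lm$it_mid) + tv, drop(R %*% lm$head_hint) + tv)
}

back_transform_line <- function(l, R, tv) {
  line3(drop(t(R) %*% (l$point - tv)), drop(t(R) %*% l$direction))
}

random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 40))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
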