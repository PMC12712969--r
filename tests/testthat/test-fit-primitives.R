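test_that("TLS line recovers exact collinear points with zero residual", {
  pts <- cbind(0, 0, 1:10)
  l <- fit_line_tls(pts)
  expect_equal(abs(l$direction), c(0, 0, 1))
  expect_equal(attr(l, "residual"), 0, tolerance = 1e-18)
  # symmetric cross: axis by symmetry
  pts2 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 5), c(0, 0, -5))
  l2 <- fit_line_tls(pts2, orient = c(0, 0, 1))
  expect_equal(l2$direction, c(0, 0, 1))
})

test_that("TLS line respects the orientation hint", {
  pts <- cbind(rnorm(20, sd = 0.01), rnorm(20, sd = 0.01), 1:20)
  up <- fit_line_tls(pts, orient = c(0, 0, 1))
  dn <- fit_line_tls(pts, orient = c(0, 0, -1))
  expect_gt(up$direction[3], 0)
  expect_lt(dn$direction[3], 0)
})

test_that("TLS residual beats random brute-force candidates", {
  set.seed(99)
  for (i in 1:10) {
    pts <- matrix(rnorm(30, sd = 2), 10, 3)
    l <- fit_line_tls(pts)
    expect_lte(attr(l, "residual"), brute_line_residual(pts, M = 1e5) + 1e-12)
  }
})

test_that("TLS line error cases raise classed conditions", {
  expect_error(fit_line_tls(matrix(1, 1, 3)), class = "fna_underdetermined")
  expect_error(fit_line_tls(matrix(2, 5, 3)), class = "fna_underdetermined")
  # perfectly isotropic square in a plane: two equal principal values
  iso <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_error(fit_line_tls(iso), class = "fna_ambiguous_direction")
})

test_that("sphere fit is exact on noiseless data including caps", {
  set.seed(12)
  th <- runif(500, 0, 2 * pi); ph <- acos(runif(500, -1, 1))
  full <- cbind(25 * sin(ph) * cos(th), 25 * sin(ph) * sin(th), 25 * cos(ph))
  full <- sweep(full, 2, c(10, 20, 30), "+")
  s <- fit_sphere(full)
  expect_equal(s$centre, c(10, 20, 30), tolerance = 1e-9)
  expect_equal(s$radius, 25, tolerance = 1e-9)
  # hemispherical cap only
  cap <- full[full[, 3] > 30, , drop = FALSE]
  s2 <- fit_sphere(cap)
  expect_equal(s2$centre, c(10, 20, 30), tolerance = 1e-6)
  expect_equal(s2$radius, 25, tolerance = 1e-6)
})

test_that("sphere fit under noise stays near the geometric refit", {
  set.seed(4)
  errs <- replicate(20, {
    th <- runif(300, 0, 2 * pi); ph <- acos(runif(300, -1, 1))
    pts <- cbind(24 * sin(ph) * cos(th), 24 * sin(ph) * sin(th), 24 * cos(ph))
    pts <- pts + matrix(rnorm(900, sd = 0.2), ncol = 3)
    alg <- fit_sphere(pts)
    # geometric (orthogonal-distance) refit oracle
    obj <- function(par) sum((sqrt(rowSums(sweep(pts, 2, par[1:3])^2)) - par[4])^2)
    geo <- stats::optim(c(alg$centre, alg$radius), obj,
                        method = "BFGS", control = list(maxit = 500))$par
    sqrt(sum((alg$centre - geo[1:3])^2))
  })
  expect_lt(mean(errs), 0.2)
})

test_that("sphere fit rejects degenerate input", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), class = "fna_underdetermined")
  planar <- cbind(rnorm(30), rnorm(30), 2)
  expect_error(fit_sphere(planar), class = "fna_singular_sphere")
})

test_that("cylinder fit recovers exact parameters on noiseless samples", {
  set.seed(8)
  th <- runif(200, 0, 2 * pi); z <- runif(200, -20, 20)
  pts <- cbind(15 * cos(th), 15 * sin(th), z)
  cyl <- fit_cylinder(pts, init = line3(c(0.5, -0.3, 0), c(0.05, -0.02, 1)))
  expect_false(cyl$degenerate)
  expect_equal(cyl$radius, 15, tolerance = 1e-6)
  expect_equal(abs(cyl$axis$direction[3]), 1, tolerance = 1e-9)
  expect_lt(point_line_distance(c(0, 0, 0), cyl$axis), 1e-6)
})

test_that("cylinder fit residual tracks the injected noise level", {
  set.seed(15)
  rms <- replicate(20, {
    th <- runif(300, 0, 2 * pi); z <- runif(300, -20, 20)
    r <- 15 + rnorm(300, sd = 0.1)
    pts <- cbind(r * cos(th), r * sin(th), z)
    fit_cylinder(pts, init = line3(c(0, 0, 0), c(0, 0, 1)))$rms_residual
  })
  expect_gt(mean(rms), 0.07)
  expect_lt(mean(rms), 0.13)
})

test_that("near-collinear clouds fall back to the TLS line", {
  pts <- cbind(rnorm(10, sd = 1e-4), rnorm(10, sd = 1e-4), 1:10)
  cyl <- fit_cylinder(pts, init = line3(c(0, 0, 0), c(0, 0, 1)))
  expect_true(cyl$degenerate)
  tls <- fit_line_tls(pts, orient = c(0, 0, 1))
  expect_equal(cyl$axis$direction, tls$direction)
  expect_equal(cyl$axis$point, tls$point)
  expect_gte(cyl$radius, 1e-6)
})
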