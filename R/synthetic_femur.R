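# Synthetic proximal-femur generator. A smooth-minimum union of implicit
# primitives (head sphere, tapered elliptical neck, shaft capsule, two
# trochanter bumps) is isosurfaced with marching tetrahedra, guaranteeing a
# watertight mesh with exactly known neck axis, head centre and landmarks.
#
# Frame convention: +z superior along the shaft axis, +x medial, +y
# anterior; the neck base sits at the origin.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic femur specification
#'
#' Geometric parameters of the generated proximal femur, all in mm and
#' degrees. Defaults approximate an adult femur: 24 mm head radius, 35 mm
#' neck tapering from 17 to 14 mm radius with mild elliptical cross-section,
#' 130 degree neck-shaft angle, 15 degrees anteversion.
#'
#' @param head_radius femoral head radius (mm).
#' @param head_offset perpendicular offset of the head centre from the neck
#'   axis (mm); 0 puts the centre exactly on the axis.
#' @param neck_length length of the neck segment (mm).
#' @param neck_radius_base,neck_radius_head neck radii at base and head end
#'   (mm, linear taper).
#' @param neck_ellipticity minor/major axis ratio of the neck cross-section.
#' @param neck_shaft_angle angle between shaft and neck axes (degrees).
#' @param anteversion anterior tilt of the neck axis (degrees).
#' @param shaft_radius,shaft_length shaft capsule radius and length (mm).
#' @param trochanter_bump_amp greater-trochanter bump radius (mm); the lesser
#'   trochanter is scaled to 0.75 of it.
#' @param vertex_noise_sigma Gaussian jitter added to mesh vertices (mm).
#' @param head_flatten_frac fraction of the head diameter cut off the distal
#'   pole to mimic head collapse (0 = intact, must be < 0.5).
#' @param voxel_pitch grid spacing for isosurfacing (mm); must resolve the
#'   neck (`pitch <= neck_radius_head / 4`).
#' @param blend smooth-union blending radius (mm).
#' @param seed integer seed for vertex noise.
#' @return An object of class `femur_spec`.
#' @export
femur_spec <- function(head_radius = 24, head_offset = 0, neck_length = 35,
                       neck_radius_base = 17, neck_radius_head = 14,
                       neck_ellipticity = 0.85, neck_shaft_angle = 130,
                       anteversion = 15, shaft_radius = 14, shaft_length = 80,
                       trochanter_bump_amp = 8, vertex_noise_sigma = 0,
                       head_flatten_frac = 0, voxel_pitch = 0.8, blend = 6,
                       seed = 20190101L) {
  sp <- as.list(environment())
  lens <- c("head_radius", "neck_length", "neck_radius_base", "neck_radius_head",
            "shaft_radius", "shaft_length", "trochanter_bump_amp", "voxel_pitch",
            "blend")
  if (any(unlist(sp[lens]) <= 0))
    fna_stop("fna_bad_spec", "all lengths must be > 0")
  if (neck_ellipticity <= 0 || neck_ellipticity > 1)
    fna_stop("fna_bad_spec", "neck_ellipticity must be in (0, 1]")
  if (head_flatten_frac < 0 || head_flatten_frac >= 0.5)
    fna_stop("fna_bad_spec", "head_flatten_frac must be in [0, 0.5)")
  if (voxel_pitch > neck_radius_head / 4)
    fna_stop("fna_resolution",
             "voxel_pitch %.2f mm too coarse to resolve the neck (limit %.2f mm)",
             voxel_pitch, neck_radius_head / 4)
  structure(sp, class = "femur_spec")
}

# Analytic construction shared by the field and the ground truth.
femur_frame <- function(spec) {
  alpha <- (180 - spec$neck_shaft_angle) * pi / 180
  av <- spec$anteversion * pi / 180
  d <- c(sin(alpha) * cos(av), sin(alpha) * sin(av), cos(alpha))  # neck axis dir
  B <- c(0, 0, 0)                                                 # neck base
  e1 <- unitize(cross3(d, c(0, 1, 0)))  # in-plane major axis (roughly coronal)
  e2 <- cross3(d, e1)                    # roughly anterior: offset direction
  t_head <- spec$neck_length +
    sqrt(max(spec$head_radius^2 - spec$neck_radius_head^2,
             (0.5 * spec$head_radius)^2))
  C <- B + t_head * d + spec$head_offset * e2
  # Greater trochanter: a capsule rising from the shaft top to a tip near
  # neck-axis level, lateral enough that cross-sections through the neck see
  # it as a separate contour (as on a real femur).
  G_a <- c(-(spec$shaft_radius + 4), -2, -10)
  G_b <- c(-(spec$shaft_radius + 10), -3, 20)
  r_g <- spec$trochanter_bump_amp
  u_l <- unitize(c(0.8, -0.6, 0))
  Lc <- (spec$shaft_radius - 1) * u_l + c(0, 0, -24)                    # lesser troch
  r_l <- 0.75 * spec$trochanter_bump_amp
  list(B = B, d = d, e1 = e1, e2 = e2, C = C,
       G_a = G_a, G_b = G_b, r_g = r_g, Lc = Lc, r_l = r_l, u_l = u_l,
       shaft_a = c(0, 0, -spec$shaft_length), shaft_b = c(0, 0, -24))
}

# Vectorized signed-distance-like fields; p is n x 3.
sdf_sphere <- function(p, c0, r) sqrt(rowSums(sweep(p, 2, c0)^2)) - r

sdf_capsule <- function(p, a, b, r) {
  ab <- b - a
  t <- pmin(pmax(drop(sweep(p, 2, a) %*% ab) / sum(ab * ab), 0), 1)
  q <- sweep(p, 2, a) - outer(t, ab)
  sqrt(rowSums(q^2)) - r
}

sdf_neck <- function(p, fr, spec) {
  rel <- sweep(p, 2, fr$B)
  tu <- drop(rel %*% fr$d)
  t <- pmin(pmax(tu, 0), spec$neck_length)
  q <- rel - outer(t, fr$d)
  a <- drop(q %*% fr$e1)
  b <- drop(q %*% fr$e2)
  rad <- sqrt(a^2 + (b / spec$neck_ellipticity)^2)
  r_t <- spec$neck_radius_base +
    (spec$neck_radius_head - spec$neck_radius_base) * t / spec$neck_length
  # capped: intersect the tapered tube with the axial slab [0, L]; the flat
  # end caps are buried inside the shaft and head blends
  pmax(rad - r_t, -tu, tu - spec$neck_length)
}

femur_field <- function(p, spec, fr = femur_frame(spec)) {
  k <- spec$blend
  f1 <- sdf_sphere(p, fr$C, spec$head_radius)
  f2 <- sdf_neck(p, fr, spec)
  f3 <- sdf_capsule(p, fr$shaft_a, fr$shaft_b, spec$shaft_radius)
  f4 <- sdf_capsule(p, fr$G_a, fr$G_b, fr$r_g)
  f5 <- sdf_sphere(p, fr$Lc, fr$r_l)
  # pairwise polynomial smooth minimum: blends only where primitives are
  # within `k` of each other, and equals the plain minimum elsewhere
  smin2 <- function(a, b) {
    h <- pmax(k - abs(a - b), 0)
    pmin(a, b) - h * h / (4 * k)
  }
  f <- Reduce(smin2, list(f1, f2, f3, f4, f5))
  if (spec$head_flatten_frac > 0) {
    # cut a distal cap off the head: intersection with a half-space
    h <- spec$head_flatten_frac * 2 * spec$head_radius
    cut <- drop(sweep(p, 2, fr$C) %*% fr$d) - (spec$head_radius - h)
    f <- pmax(f, cut)
  }
  f
}

# primitive fields separately, for head-vertex tagging
femur_field_parts <- function(p, spec, fr = femur_frame(spec)) {
  cbind(head = sdf_sphere(p, fr$C, spec$head_radius),
        neck = sdf_neck(p, fr, spec),
        shaft = sdf_capsule(p, fr$shaft_a, fr$shaft_b, spec$shaft_radius),
        gt = sdf_capsule(p, fr$G_a, fr$G_b, fr$r_g),
        lt = sdf_sphere(p, fr$Lc, fr$r_l))
}

# march from `start` along unit `dir` until the field crosses zero, then
# bisect; exact surface-point construction for landmarks
surface_point <- function(spec, fr, start, dir, max_dist = 60) {
  dir <- unitize(dir)
  fval <- function(t) femur_field(matrix(start + t * dir, 1, 3), spec, fr)
  t0 <- 0
  if (fval(0) >= 0) fna_stop("fna_bad_spec", "surface march must start inside")
  t1 <- max_dist
  ts <- seq(0.5, max_dist, by = 0.5)
  fs <- femur_field(matrix(start, nrow = length(ts), ncol = 3, byrow = TRUE) +
                    outer(ts, dir), spec, fr)
  hit <- which(fs >= 0)
  if (length(hit) == 0L) fna_stop("fna_bad_spec", "surface march never exits")
  t1 <- ts[hit[1]]; t0 <- if (hit[1] > 1) ts[hit[1] - 1] else 0
  for (i in 1:40) {
    tm <- (t0 + t1) / 2
    if (fval(tm) < 0) t0 <- tm else t1 <- tm
  }
  start + ((t0 + t1) / 2) * dir
}

#' Generate a synthetic proximal femur with known ground truth
#'
#' @param spec a [femur_spec()].
#' @return A list with `mesh` (watertight [trimesh()]) and `truth`, a list
#'   holding `neck_axis` ([line3()]), `head_centre`, `head_radius`,
#'   `landmarks` ([landmark_set()]) and `head_vertex_tags` (logical, one per
#'   mesh vertex, `TRUE` where the vertex lies on the pure spherical head
#'   surface, outside the influence of the neck blend).
#' @export
generate_femur <- function(spec = femur_spec()) {
  if (!inherits(spec, "femur_spec")) fna_stop("fna_bad_spec", "need a femur_spec")
  fr <- femur_frame(spec)
  pad <- spec$blend + 3 * spec$voxel_pitch
  lo <- pmin(fr$C - spec$head_radius,
             fr$shaft_a - spec$shaft_radius,
             fr$G_a - fr$r_g, fr$G_b - fr$r_g, fr$Lc - fr$r_l) - pad
  hi <- pmax(fr$C + spec$head_radius,
             fr$shaft_b + spec$shaft_radius,
             fr$G_a + fr$r_g, fr$G_b + fr$r_g, fr$Lc + fr$r_l) + pad
  xs <- seq(lo[1], hi[1], by = spec$voxel_pitch)
  ys <- seq(lo[2], hi[2], by = spec$voxel_pitch)
  zs <- seq(lo[3], hi[3], by = spec$voxel_pitch)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  fld <- array(femur_field(grid, spec, fr), c(length(xs), length(ys), length(zs)))
  mesh <- marching_tetrahedra(fld, xs, ys, zs)
  if (spec$vertex_noise_sigma > 0) {
    mesh$vertices <- mesh$vertices + with_seed(spec$seed,
      matrix(stats::rnorm(length(mesh$vertices), sd = spec$vertex_noise_sigma),
             ncol = 3))
  }
  # tag head vertices where the head sphere dominates every other primitive
  # by at least half the blend radius: there the blended surface deviates
  # from the pure sphere by under blend/16, so these are genuinely head
  parts <- femur_field_parts(mesh$vertices, spec, fr)
  other <- do.call(pmin, as.data.frame(parts[, -1, drop = FALSE]))
  tags <- parts[, "head"] < other - spec$blend / 2

  # Trochanter apices: extremal surface points along the neck direction, so
  # the landmark plane supports the trochanteric mass (as on a real femur,
  # where everything but neck and head lies behind the intertrochanteric
  # plane).
  gt_tip <- surface_point(spec, fr, fr$G_b, fr$d)
  lt_tip <- surface_point(spec, fr, fr$Lc, fr$d)
  # anterior neck-base surface point between the trochanters
  it_mid <- surface_point(spec, fr, fr$B + 1 * fr$d, c(0, 1, 0))
  lms <- landmark_set(gt_tip, lt_tip, it_mid, fr$C)

  truth <- list(neck_axis = line3(fr$B, fr$d), head_centre = fr$C,
                head_radius = spec$head_radius, landmarks = lms,
                head_vertex_tags = tags, spec = spec)
  list(mesh = mesh, truth = truth)
}

#' Perturb landmarks with isotropic Gaussian noise
#'
#' Simulates observer variability in landmark picking; `head_hint` is left
#' unchanged (it only orients directions).
#'
#' @param lm a [landmark_set()].
#' @param sigma isotropic noise standard deviation per coordinate (mm).
#' @param seed integer seed.
#' @return A perturbed [landmark_set()].
#' @export
perturb_landmarks <- function(lm, sigma, seed = 20190101L) {
  if (sigma < 0) fna_stop("fna_bad_config", "sigma must be >= 0")
  if (sigma == 0) return(lm)
  noise <- with_seed(seed, matrix(stats::rnorm(9, sd = sigma), 3, 3))
  landmark_set(lm$gt_tip + noise[1, ], lm$lt_tip + noise[2, ],
               lm$it_mid + noise[3, ], lm$head_hint)
}
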