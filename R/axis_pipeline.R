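# The centroid iterative method. The plane through the greater-trochanter
# tip, lesser-trochanter tip and intertrochanteric-line midpoint seeds a
# stack of equally spaced cross-sections translated toward the femoral head;
# each section's polygon centroid is computed, a total-least-squares line is
# fitted to the centroid cloud, and slicing is repeated perpendicular to the
# fitted line. After the final iteration a cylinder is fitted to the centroid
# cloud and its axis is the femoral neck axis (FNA). The head is fitted as a
# sphere; the distance between head centre and FNA (DBHF) quantifies
# accuracy.

#' Landmark set seeding the initial section
#'
#' Three anatomical points define the initial section plane; `head_hint` (any
#' point on the femoral-head side, typically an approximate head centre) only
#' resolves orientation ambiguities and need not be precise.
#'
#' @param gt_tip tip of the greater trochanter (mm).
#' @param lt_tip tip of the lesser trochanter (mm).
#' @param it_mid midpoint of the intertrochanteric line (mm).
#' @param head_hint any point on the head side of the landmark plane (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(gt_tip, lt_tip, it_mid, head_hint) {
  lm <- structure(list(gt_tip = as_p3(gt_tip), lt_tip = as_p3(lt_tip),
                       it_mid = as_p3(it_mid), head_hint = as_p3(head_hint)),
                  class = "landmark_set")
  pl <- plane_from_points(lm$gt_tip, lm$lt_tip, lm$it_mid)  # rejects collinear
  if (abs(plane_signed_distance(lm$head_hint, pl)) < 1e-6)
    fna_stop("fna_degenerate_landmarks",
             "head_hint lies on the landmark plane; orientation undefined")
  lm
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in c("gt_tip", "lt_tip", "it_mid", "head_hint"))
    cat(sprintf("  %-9s (%.2f, %.2f, %.2f)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Section-stack configuration
#'
#' Defaults follow the measurement protocol: 10 sections spaced 1 mm apart,
#' five iterations.
#'
#' @param n_sections number of parallel sections per iteration (`>= 3`).
#' @param spacing section spacing in mm (`> 0`).
#' @param n_iterations number of re-slicing iterations (`>= 1`).
#' @param early_stop_deg if positive, stop early once successive axes differ
#'   by less than this angle (degrees). Off (`0`) by default so the fixed
#'   iteration count is honoured exactly.
#' @param cylinder_source `"centroids"` fits the final cylinder to the last
#'   iteration's section centroids; `"all_centroids"` accumulates every
#'   iteration's centroids; `"contours"` uses the last iteration's contour
#'   surface points.
#' @return An object of class `section_config`.
#' @export
section_config <- function(n_sections = 10L, spacing = 1.0, n_iterations = 5L,
                           early_stop_deg = 0,
                           cylinder_source = c("centroids", "all_centroids", "contours")) {
  cylinder_source <- match.arg(cylinder_source)
  if (n_sections < 3L) fna_stop("fna_bad_config", "n_sections must be >= 3")
  if (spacing <= 0) fna_stop("fna_bad_config", "spacing must be > 0")
  if (n_iterations < 1L) fna_stop("fna_bad_config", "n_iterations must be >= 1")
  structure(list(n_sections = as.integer(n_sections), spacing = spacing,
                 n_iterations = as.integer(n_iterations),
                 early_stop_deg = early_stop_deg,
                 cylinder_source = cylinder_source),
            class = "section_config")
}

#' Initial section plane from the landmarks
#'
#' Plane through the three landmark points, with the normal oriented so that
#' `head_hint` lies on the positive side (sections are translated along
#' `+normal`, i.e. toward the head).
#'
#' @param landmarks a [landmark_set()].
#' @return A [plane3()].
#' @export
initial_plane <- function(landmarks) {
  pl <- plane_from_points(landmarks$gt_tip, landmarks$lt_tip, landmarks$it_mid)
  if (plane_signed_distance(landmarks$head_hint, pl) < 0)
    pl <- plane3(pl$origin, -pl$normal)
  pl
}

#' Build a stack of parallel sections and their centroids
#'
#' Translates `base` by offsets `spacing, 2*spacing, ..., n_sections*spacing`
#' along its `+normal`, slices the mesh at each offset, selects the neck
#' contour nearest the running reference point (starting from `reference`),
#' and computes each contour's centroid.
#'
#' @param mesh a watertight [trimesh()].
#' @param base a [plane3()]; sections are offset from it toward `+normal`.
#' @param cfg a [section_config()].
#' @param reference length-3 neck-side seed point used to select the first
#'   section's contour.
#' @return List with `contours` (list of `section_contour`) and `centroids`
#'   (k x 3 matrix, one row per successful section, in offset order).
#' @export
build_section_stack <- function(mesh, base, cfg, reference) {
  ref <- as_p3(reference)
  contours <- vector("list", cfg$n_sections)
  cent <- matrix(NA_real_, cfg$n_sections, 3)
  n_ok <- 0L
  for (k in seq_len(cfg$n_sections)) {
    pl <- plane3(base$origin + k * cfg$spacing * base$normal, base$normal)
    cs <- slice_mesh(mesh, pl)
    if (length(cs) == 0L) break
    sel <- select_neck_contour(cs, ref)
    contours[[k]] <- sel
    cent[k, ] <- sel$centroid3d
    ref <- sel$centroid3d
    n_ok <- k
  }
  if (n_ok < 3L)
    fna_stop("fna_stack_truncated",
             "only %d of %d sections produced contours; cannot fit an axis",
             n_ok, cfg$n_sections)
  if (n_ok < cfg$n_sections)
    warning(sprintf("section stack truncated: %d of %d sections succeeded",
                    n_ok, cfg$n_sections), call. = FALSE)
  list(contours = contours[seq_len(n_ok)],
       centroids = cent[seq_len(n_ok), , drop = FALSE])
}

#' Run the centroid iterative axis fit
#'
#' Iteration 1 slices parallel to the initial landmark plane; each subsequent
#' iteration re-slices perpendicular to the previous iteration's fitted line,
#' with the stack re-anchored at the previous stack's first centroid. After
#' the final iteration a cylinder is fitted to the centroid cloud and its
#' axis taken as the FNA.
#'
#' @param mesh a watertight [trimesh()].
#' @param landmarks a [landmark_set()].
#' @param cfg a [section_config()].
#' @return An object of class `fna_fit` with fields `fna` ([line3()]),
#'   `cylinder`, `per_iteration_axes`, `centroids` (list of per-iteration
#'   matrices), `last_contours`, `last_offset` (axial coordinate of the last
#'   section on the FNA) and `config`. Head sphere and DBHF are added by
#'   [fit_fna()].
#' @export
iterate_axis <- function(mesh, landmarks, cfg = section_config()) {
  assert_watertight(mesh)
  base <- initial_plane(landmarks)
  toward_head <- base$normal
  # seed contour selection at the landmark centroid (a neck-base point);
  # the head hint projects too far off-axis when the landmark plane is tilted
  ref <- base$origin
  axes <- vector("list", cfg$n_iterations)
  cent_list <- vector("list", cfg$n_iterations)
  stack <- NULL
  n_done <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    stack <- build_section_stack(mesh, base, cfg, ref)
    line_it <- fit_line_tls(stack$centroids, orient = toward_head)
    axes[[it]] <- line_it
    cent_list[[it]] <- stack$centroids
    n_done <- it
    if (it < cfg$n_iterations) {
      if (cfg$early_stop_deg > 0 && it > 1L &&
          angle_between_lines(line_it, axes[[it - 1L]]) < cfg$early_stop_deg) break
      anchor <- stack$centroids[1, ]
      base <- plane3(anchor, line_it$direction)
      toward_head <- line_it$direction
      ref <- anchor
    }
  }
  axes <- axes[seq_len(n_done)]
  cent_list <- cent_list[seq_len(n_done)]

  cyl_pts <- switch(cfg$cylinder_source,
    centroids = cent_list[[n_done]],
    all_centroids = do.call(rbind, cent_list),
    contours = do.call(rbind, lapply(stack$contours, function(ct) ct$loop))
  )
  cyl <- fit_cylinder(cyl_pts, init = axes[[n_done]])
  fna <- cyl$axis
  if (sum(fna$direction * axes[[n_done]]$direction) < 0)
    fna <- line3(fna$point, -fna$direction)

  structure(list(
    fna = fna, cylinder = cyl, per_iteration_axes = axes,
    centroids = cent_list, last_contours = stack$contours,
    last_offset = max(line_axial_coord(cent_list[[n_done]], fna)),
    config = cfg, landmarks = landmarks
  ), class = "fna_fit")
}

#' Select femoral-head surface vertices
#'
#' Candidate vertices lie beyond the last section plane along the FNA (head
#' side) and within `radial_factor` times the `radial_quantile` quantile of
#' the final contours' radial distances from the axis. Because the neck
#' itself extends beyond the sections, the candidate set is refined by two
#' trimmed sphere refits that keep only vertices near the current sphere
#' surface.
#'
#' @param mesh a [trimesh()].
#' @param fit an `fna_fit` from [iterate_axis()].
#' @param radial_factor multiple of the contour radial quantile admitted
#'   radially (default 2; the head radius exceeds the neck radius, so a
#'   tighter factor clips the head equator and biases the sphere fit).
#' @param radial_quantile quantile of contour radial distances used as the
#'   radial scale (default 0.95).
#' @param trim_mm sequence of surface-band half-widths (mm) for the trimmed
#'   refits.
#' @return Matrix of selected vertex coordinates.
#' @export
select_head_vertices <- function(mesh, fit, radial_factor = 2,
                                 radial_quantile = 0.95,
                                 trim_mm = c(3, 1.5, 0.8, 0.6)) {
  fna <- fit$fna
  v <- mesh$vertices
  t_ax <- line_axial_coord(v, fna)
  r_ax <- point_line_distance(v, fna)
  loop_pts <- do.call(rbind, lapply(fit$last_contours, function(ct) ct$loop))
  r_scale <- stats::quantile(point_line_distance(loop_pts, fna), radial_quantile,
                             names = FALSE)
  keep <- t_ax > fit$last_offset & r_ax < radial_factor * r_scale
  if (sum(keep) < 10L)
    fna_stop("fna_head_not_found",
             "no femoral head beyond the section stack (only %d candidate vertices)",
             sum(keep))
  cand <- v[keep, , drop = FALSE]
  # Trimmed refits against the full candidate set: each pass refits the
  # sphere to the current inliers and re-selects inliers among all
  # candidates, so points discarded under an early biased fit can return.
  sel <- cand
  for (band in trim_mm) {
    sph <- fit_sphere(sel)
    d <- abs(sqrt(rowSums(sweep(cand, 2, sph$centre)^2)) - sph$radius)
    if (sum(d < band) >= 10L) sel <- cand[d < band, , drop = FALSE]
  }
  # The head-neck junction bulges outward where the surfaces blend, which
  # biases a sphere fitted to everything. Refit using only vertices away
  # from the neck-side pole, then take as the head every candidate close to
  # that unbiased sphere.
  for (i in 1:2) {
    sph <- fit_sphere(sel)
    t_rel <- drop(sweep(cand, 2, sph$centre) %*% fna$direction)
    d <- abs(sqrt(rowSums(sweep(cand, 2, sph$centre)^2)) - sph$radius)
    fitset <- cand[d < 1 & t_rel > -0.3 * sph$radius, , drop = FALSE]
    if (nrow(fitset) >= 10L) sel <- fitset
  }
  sph <- fit_sphere(sel)
  d <- abs(sqrt(rowSums(sweep(cand, 2, sph$centre)^2)) - sph$radius)
  out <- cand[d < 0.5, , drop = FALSE]
  # sanity: the selection must look like a spherical head, not a neck stump:
  # inliers should cover most of the candidate surface and span the sphere
  # axially (a tube or rim ring concentrates in a narrow band)
  frac <- nrow(out) / nrow(cand)
  spread <- diff(range(line_axial_coord(out, fna)))
  if (nrow(out) < 10L || frac < 0.35 || spread < 1.2 * sph$radius ||
      sph$radius > 6 * r_scale)
    fna_stop("fna_head_not_found",
             "selected surface beyond the sections does not resemble a femoral head (inlier fraction %.2f, axial spread %.1f mm, radius %.1f mm)",
             frac, spread, sph$radius)
  out
}

#' Distance between head centre and fitted axis (DBHF)
#'
#' @param fit an `fna_fit` that already carries `head_sphere`.
#' @return DBHF in mm.
#' @export
evaluate_accuracy <- function(fit) {
  if (is.null(fit$head_sphere))
    fna_stop("fna_bad_config", "fit has no head sphere; run fit_fna()")
  point_line_distance(fit$head_sphere$centre, fit$fna)
}

#' Full axis-fitting pipeline
#'
#' Runs [iterate_axis()], selects head vertices, fits the head sphere, and
#' computes DBHF.
#'
#' @inheritParams iterate_axis
#' @param radial_factor,radial_quantile passed to [select_head_vertices()].
#' @return An `fna_fit` with `head_sphere` ([fit_sphere()] result) and
#'   `dbhf` (mm) populated.
#' @export
fit_fna <- function(mesh, landmarks, cfg = section_config(),
                    radial_factor = 2, radial_quantile = 0.95) {
  fit <- iterate_axis(mesh, landmarks, cfg)
  head_pts <- select_head_vertices(mesh, fit, radial_factor = radial_factor,
                                   radial_quantile = radial_quantile)
  fit$head_sphere <- fit_sphere(head_pts)
  fit$n_head_vertices <- nrow(head_pts)
  fit$dbhf <- evaluate_accuracy(fit)
  fit
}

#' @export
print.fna_fit <- function(x, ...) {
  cat(sprintf("Centroid iterative FNA fit (%d iterations, %d x %.1f mm sections)\n",
              length(x$per_iteration_axes), x$config$n_sections, x$config$spacing))
  cat("FNA: "); print(x$fna)
  if (!is.null(x$head_sphere)) {
    cat(sprintf("Head centre (%.2f, %.2f, %.2f), radius %.2f mm\n",
                x$head_sphere$centre[1], x$head_sphere$centre[2],
                x$head_sphere$centre[3], x$head_sphere$radius))
    cat(sprintf("DBHF: %.3f mm\n", x$dbhf))
  }
  invisible(x)
}

#' Rotate an axis to simulate a deviated FNA
#'
#' Rotates the line direction by `angle_deg` within the rotation plane,
#' keeping the axis point; `rotation_plane_normal` is first projected
#' perpendicular to the axis direction so the deviated axis differs from the
#' original by exactly `angle_deg`. Used to construct the deviated-axis
#' scenario in which the FNA is rotated by a fixed angle.
#'
#' @param fna a [line3()].
#' @param angle_deg rotation angle in degrees, `|angle| < 90`.
#' @param rotation_plane_normal unit vector normal to the rotation plane; must
#'   not be parallel to the axis direction.
#' @return The rotated [line3()].
#' @export
deviated_axis <- function(fna, angle_deg, rotation_plane_normal) {
  if (abs(angle_deg) >= 90)
    fna_stop("fna_bad_config", "|angle_deg| must be < 90")
  k <- unitize(as_p3(rotation_plane_normal))
  if (vnorm(cross3(k, fna$direction)) < 1e-9)
    fna_stop("fna_undefined_rotation",
             "rotation_plane_normal is parallel to the axis; rotation undefined")
  k <- unitize(k - sum(k * fna$direction) * fna$direction)
  line3(fna$point, rotate_about_axis(fna$direction, k, angle_deg))
}
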