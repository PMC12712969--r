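# Mesh-plane slicing: intersect a watertight triangle mesh with a plane,
# chain the crossing segments into closed loops, and compute each loop's
# area-weighted centroid in 3D.
#
# Edge-crossing vertices are keyed by the (sorted) vertex-index pair of the
# crossed mesh edge, never by coordinate rounding, so loop chaining needs no
# epsilon tuning. Triangles lying exactly in the plane are a measure-zero
# event handled by nudging the plane 1e-7 mm along its normal and retrying
# once.

#' Intersect a mesh with a plane
#'
#' Returns one `section_contour` per closed intersection loop. Loop vertices
#' are ordered counter-clockwise when viewed from the `+normal` side; segment
#' endpoints are linearly interpolated along crossing mesh edges.
#'
#' @param mesh a watertight [trimesh()].
#' @param plane a [plane3()].
#' @return A list of `section_contour` objects (empty if the plane misses
#'   the mesh). Each has fields `plane`, `loop` (k x 3 matrix on the plane),
#'   `loop2d` (k x 2 chart coordinates), `area` (mm^2) and `centroid3d`.
#' @export
slice_mesh <- function(mesh, plane) {
  res <- slice_mesh_once(mesh, plane)
  if (identical(res, "degenerate")) {
    nudged <- plane3(plane$origin + 1e-7 * plane$normal, plane$normal)
    res <- slice_mesh_once(mesh, nudged)
    if (identical(res, "degenerate"))
      fna_stop("fna_degenerate_slice",
               "plane still contains mesh vertices after nudging; mesh may be corrupt")
  }
  res
}

slice_mesh_once <- function(mesh, plane) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- plane_signed_distance(v, plane)
  if (any(abs(s) < 1e-12)) return("degenerate")

  pos <- s > 0
  fp <- matrix(pos[f], ncol = 3)
  ncross <- abs(fp[, 1] + fp[, 2] + fp[, 3] - 1.5) < 1  # 1 or 2 vertices positive
  if (!any(ncross)) return(list())
  fc <- f[ncross, , drop = FALSE]
  fpc <- fp[ncross, , drop = FALSE]

  # For each crossing face, the two crossed edges (as vertex-index pairs).
  # Edge opposite the lone-signed vertex does not cross.
  lone <- integer(nrow(fc))
  one_pos <- rowSums(fpc) == 1L
  lone[one_pos] <- max.col(fpc[one_pos, , drop = FALSE], ties.method = "first")
  lone[!one_pos] <- max.col(!fpc[!one_pos, , drop = FALSE], ties.method = "first")
  o1 <- cbind(fc[cbind(seq_len(nrow(fc)), lone)],
              fc[cbind(seq_len(nrow(fc)), lone %% 3L + 1L)])
  o2 <- cbind(fc[cbind(seq_len(nrow(fc)), lone)],
              fc[cbind(seq_len(nrow(fc)), (lone + 1L) %% 3L + 1L)])

  nv <- nrow(v) + 1
  key1 <- pmin(o1[, 1], o1[, 2]) * nv + pmax(o1[, 1], o1[, 2])
  key2 <- pmin(o2[, 1], o2[, 2]) * nv + pmax(o2[, 1], o2[, 2])
  keys <- unique(c(key1, key2))
  id1 <- match(key1, keys)
  id2 <- match(key2, keys)

  # Interpolated 3D position of each unique edge crossing
  ia <- floor(keys / nv); ib <- keys - ia * nv
  t <- s[ia] / (s[ia] - s[ib])
  pts <- v[ia, , drop = FALSE] + t * (v[ib, , drop = FALSE] - v[ia, , drop = FALSE])

  # Chain segments (id1[i] -- id2[i]) into loops; watertight mesh => every
  # crossing vertex has degree exactly 2.
  nseg <- length(id1)
  deg_ok <- tabulate(c(id1, id2), nbins = length(keys))
  if (any(deg_ok != 2L)) {
    open_ids <- which(deg_ok != 2L)
    gap <- if (length(open_ids) >= 2)
      min(dist(pts[open_ids, , drop = FALSE])) else NA_real_
    fna_stop("fna_unclosed_contour",
             "open intersection chain (mesh not watertight at the slice); %d loose ends, smallest gap %.3g mm",
             length(open_ids), gap)
  }
  # adjacency: for each vertex id, its two incident segments
  seg_of <- cbind(rep(seq_len(nseg), 2L), c(id1, id2))
  ord <- order(seg_of[, 2])
  seg_sorted <- seg_of[ord, 1]
  adj <- matrix(seg_sorted, nrow = 2)  # column j = segments at vertex j

  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    cur_seg <- start
    cur_vert <- id1[start]
    loop_ids <- integer(0)
    repeat {
      used[cur_seg] <- TRUE
      loop_ids <- c(loop_ids, cur_vert)
      nxt_vert <- if (id1[cur_seg] == cur_vert) id2[cur_seg] else id1[cur_seg]
      two <- adj[, nxt_vert]
      nxt_seg <- if (two[1] == cur_seg) two[2] else two[1]
      cur_vert <- nxt_vert
      cur_seg <- nxt_seg
      if (used[cur_seg] && cur_vert == id1[start]) break
      if (used[cur_seg]) break  # defensive; cannot happen on degree-2 graphs
    }
    loops[[length(loops) + 1L]] <- loop_ids
  }

  basis <- plane_basis(plane)
  out <- lapply(loops, function(ids) {
    if (length(ids) < 3L) return(NULL)
    p3 <- pts[ids, , drop = FALSE]
    rel <- sweep(p3, 2, plane$origin)
    p2 <- cbind(drop(rel %*% basis$e1), drop(rel %*% basis$e2))
    ctr <- tryCatch(polygon_centroid(p2), fnaxis_error = function(e) NULL)
    if (is.null(ctr)) return(NULL)
    if (attr(ctr, "signed_area") < 0) {  # normalize winding to CCW from +normal
      p3 <- p3[rev(seq_len(nrow(p3))), , drop = FALSE]
      p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
      ctr <- polygon_centroid(p2)
    }
    c3 <- plane$origin + ctr[1] * basis$e1 + ctr[2] * basis$e2
    structure(list(plane = plane, loop = p3, loop2d = p2,
                   area = attr(ctr, "area"), centroid3d = c3),
              class = "section_contour")
  })
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("<section_contour> %d vertices, area %.2f mm^2, centroid (%.2f, %.2f, %.2f)\n",
              nrow(x$loop), x$area, x$centroid3d[1], x$centroid3d[2], x$centroid3d[3]))
  invisible(x)
}

#' Select the neck contour from a slice
#'
#' A plane through the proximal femur can cut the neck, the shaft and the
#' trochanters at once. The neck contour is taken as the one whose centroid
#' lies nearest a reference point (the previous section's centroid, or the
#' projected head hint for the first section); ties within 1e-6 mm go to the
#' larger area.
#'
#' @param contours list of `section_contour` from [slice_mesh()].
#' @param reference length-3 point (mm).
#' @return The selected `section_contour`.
#' @export
select_neck_contour <- function(contours, reference) {
  if (length(contours) == 0L)
    fna_stop("fna_no_contour", "no contours to select from (plane missed the mesh)")
  reference <- as_p3(reference)
  # drop negligible contours (noise speckles where a jittered surface grazes
  # the plane): absolute floor 1 mm^2, relative floor 0.5% of the largest
  areas_all <- vapply(contours, function(ct) ct$area, numeric(1))
  keep <- areas_all >= max(1, 0.005 * max(areas_all))
  if (any(keep)) contours <- contours[keep]
  d <- vapply(contours, function(ct) vnorm(ct$centroid3d - reference), numeric(1))
  best <- which(d <= min(d) + 1e-6)
  if (length(best) > 1L) {
    areas <- vapply(contours[best], function(ct) ct$area, numeric(1))
    best <- best[which.max(areas)]
  }
  contours[[best[1]]]
}

#' 3D centroid of a section contour
#'
#' The loop is projected into an orthonormal in-plane chart, the lamina
#' centroid computed by [polygon_centroid()], and the result mapped back to
#' 3D (it lies on the section plane by construction).
#'
#' @param contour a `section_contour`.
#' @return Length-3 point (mm).
#' @export
section_centroid <- function(contour) {
  contour$centroid3d
}
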