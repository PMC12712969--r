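---
title: "Fitting the femoral neck axis by the centroid iterative method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting the femoral neck axis by the centroid iterative method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnaxis)
```

## The problem

The femoral neck axis (FNA) is the reference axis for femoral neck
rotational osteotomy, a hip-preservation procedure in which the femoral
head is rotated about the neck axis to move necrotic bone out of the
weight-bearing zone. The axis is not directly observable: it must be
estimated from the reconstructed bone surface. `fnaxis` implements the
centroid iterative method for this estimation, together with the accuracy
metric and reliability statistics used to evaluate it, and a synthetic-femur
generator that provides ground truth the clinical data cannot.

## The method

The input is a watertight triangle mesh of the proximal femur (millimetres,
any rigid frame) and four landmark points: the tip of the greater
trochanter, the tip of the lesser trochanter, the midpoint of the
intertrochanteric line, and a rough head-side hint used only to orient
directions.

1. **Initial section.** The plane through the three anatomical landmarks is
   the initial section. Its normal is oriented toward the femoral head; on a
   real femur this plane is approximately a supporting plane of the
   trochanteric mass, so the bone on its head side is essentially the neck.
2. **Section stack.** The plane is translated along its normal in 10 steps
   of 1 mm. Each translated plane is intersected with the mesh; the
   intersection loops are assembled exactly (edge-interpolated crossing
   points, chained by shared mesh-edge identity), and the loop nearest a
   running reference point is taken as the neck contour. The first section's
   reference is the landmark-plane centroid; each later section uses the
   previous section's centroid. Contours below 1 mm² (or 0.5% of the largest
   loop in the slice) are ignored as numerical speckles.
3. **Centroid line.** Each contour is projected into an orthonormal chart of
   its plane and its area-weighted (lamina) centroid computed by the
   shoelace formulas. A total-least-squares line — the line through the
   centroid-cloud mean along the leading principal direction — minimizes the
   summed squared perpendicular distances.
4. **Iteration.** Slicing is repeated perpendicular to the fitted line,
   re-anchored at the previous stack's first centroid, five times in total.
   An optional early stop (successive axes within a threshold angle) is off
   by default so the fixed five iterations are honoured exactly.
5. **Cylinder.** A cylinder is fitted to the final centroid cloud
   (Levenberg–Marquardt over axis point, axis direction and radius,
   minimizing radial-distance residuals) and its axis is the FNA. Converged
   centroid clouds are nearly collinear, which makes the radius
   unidentifiable; below 0.1 mm RMS radial spread the cylinder fit returns
   the total-least-squares line directly (flagged `degenerate`), preserving
   the axis, which is the only quantity used downstream.
6. **Accuracy (DBHF).** The femoral head is fitted as a sphere (algebraic
   linear least squares, exact on noiseless data including partial caps).
   The distance between the fitted head centre and the FNA — DBHF — is the
   accuracy metric: under the mechanical-equilibrium assumption the ideal
   head centre lies on the neck axis.

```{r example}
fem <- generate_femur(femur_spec(voxel_pitch = 1.5))
fit <- fit_fna(fem$mesh, fem$truth$landmarks)
fit
angle_between_lines(fit$fna, fem$truth$neck_axis)
```

## Head-vertex selection

The surface points feeding the sphere fit are not prescribed by the
measurement protocol, so the package defines them. Candidates are mesh
vertices beyond the last section plane along the FNA and within 2 times the
0.95 quantile of the final contours' radial distances (the head radius
exceeds the neck radius by enough that a tighter radial window clips the
head equator and biases the algebraic fit). Because the neck itself extends
beyond the sections, the candidate set is refined by trimmed sphere refits
(bands 3, 1.5, 0.8, 0.6 mm, re-selected from the full candidate set each
pass), followed by two refits that exclude vertices near the neck-side pole,
where the head–neck junction blends outward and would otherwise bias the
centre along the axis. The final selection is every candidate within 0.5 mm
of the unbiased sphere. A selection whose inlier fraction is low, whose
axial extent is under 1.2 sphere radii, or whose radius is implausibly large
raises a head-not-found error rather than returning a stump fit — a mesh
truncated below the head fails loudly.

## The synthetic femur

Patient CT reconstructions offer no ground truth, so validation uses a
constructed femur: a smooth union (pairwise polynomial smooth-minimum,
6 mm blending radius so the head–neck junction resembles anatomy and never
pinches) of a head sphere, a tapered elliptical neck, a shaft capsule and
two trochanteric bumps, isosurfaced by marching tetrahedra on a regular
grid. The Kuhn-tetrahedra decomposition is translation-invariant, so the
extracted surface is watertight by construction — every slice produces
closed loops. The neck axis, head centre (optionally offset perpendicular
to the axis by `head_offset`), head radius and landmarks are recorded from
the construction before meshing, exactly.

Default dimensions approximate an adult femur: 24 mm head radius, 35 mm
neck tapering from 17 to 14 mm radius with 0.85 ellipticity, 130° neck-shaft
angle, 15° anteversion, 14 mm × 80 mm shaft, 0.8 mm voxel pitch. The
trochanteric prominences are placed so that the landmark plane has the
supporting-plane property of real anatomy, with the greater trochanter far
enough laterally that neck sections see it as a separate contour; the
resulting initial plane is tilted roughly 14° from the true axis. This
matters: the five-iteration scheme contracts to the true axis from initial
tilts up to roughly 15°, which is the regime the anatomical landmarks
provide, but it is not globally convergent, and synthetic geometries whose
landmark plane is far steeper leave the domain the method is designed for.
Landmark apices are defined constructively as surface-extremal points along
the neck direction — a simulation convention standing in for the anatomical
definitions.

What the generator does not emulate: cortical/trabecular density structure
(sections are isodensity contours of a surface model, not CT), osteophytes
and pathology beyond a flattened head cap (`head_flatten_frac`, which only
stresses the sphere fit), inter-patient shape statistics, and segmentation
artefacts. Passing tests therefore demonstrate correctness of the geometry
pipeline and estimator under controlled conditions, not clinical accuracy.

`head_vertex_tags` marks vertices where the head sphere dominates every
other primitive by at least half the blending radius; there the blended
surface deviates from the pure sphere by under 0.4 mm, so the tags give a
conservative ground-truth head region for evaluating vertex selection.

## Reliability statistics

Repeated measurements (cases × raters or repetitions) are summarized by the
intraclass correlation coefficient in its two-way random-effects,
absolute-agreement, single-measure form — ICC(2,1) — with a 95% confidence
interval from the F-distribution bounds (Satterthwaite degrees of freedom
for the composite denominator). This form matches the repeated-measures
design in which the same cases are measured by each rater; the output
records the model tag and the mean squares for audit. A zero-variance table
raises an undefined-ICC error rather than silently returning 1.

Gender × side comparisons of DBHF use a two-way ANOVA with interaction.
Unbalanced designs (such as a 27/23 gender split) use Type II sums of
squares, the conventional default absent interaction evidence; balanced
designs reduce to the classical decomposition, which the tests verify
against longhand cell-means arithmetic. Noise-free constructed designs with
zero residual variance report `F = Inf, p = 0` for genuinely loaded terms
and `F = 0, p = 1` for unloaded ones.

`simulate_reliability_study()` closes the loop: it generates jittered cases
(head-offset and neck-shaft-angle variation supply between-case variance),
perturbs the landmarks per rater/repetition with isotropic Gaussian noise
(`sigma_rater`, default 0.5 mm — a simulation choice; observer variability
was not quantified in the source protocol), runs the full pipeline for
every cell, and returns the DBHF table. With between-case variance
dominating, estimated ICCs concentrate near 1, mirroring the high-ICC
regime reported for the method.

## Numerical choices

* Degeneracy tolerances are fixed, not user-configurable: 1e-6 mm² minimum
  landmark-triangle area, 1e-9 unit-norm tolerance, 1e-9 mm² minimum polygon
  area. They guard numerical validity, not modelling decisions.
* Slicing keys crossing vertices by mesh-edge identity, never by coordinate
  rounding; a plane containing mesh vertices is nudged 1e-7 mm along its
  normal and re-sliced once.
* Marching tetrahedra clamps |field| values below 1e-4 mm away from zero
  (sign-preserving) so crossing vertices cannot collapse under float32
  quantization when meshes are written to STL.
* Non-watertight meshes are rejected with an error, never repaired: silent
  hole-filling would corrupt section centroids.
* Contour winding is normalized counter-clockwise viewed from the +normal,
  making signed-area formulas sign-safe.
* All randomness flows through explicit integer seeds; the generator and
  pipeline are deterministic given spec and seed, and rigid-transform
  equivariance of the fit is exact to floating-point.

## Problem sizes used in validation

The default 0.8 mm voxel pitch is used where absolute accuracy is asserted
(axis recovery within 1°, DBHF within 0.3 mm). Studies that run the
pipeline many times use coarser grids, chosen because the quantities they
measure are insensitive to meshing resolution: 1.2 mm for the head-offset
recovery sweep (10 anatomy-jittered femurs per offset), 1.0 mm for the
20-femur vertex-noise comparison of one versus five iterations, and 1.8 mm
inside `simulate_reliability_study()` (50 replicate 10-case × 3-repetition
studies), where only relative variance components matter. ANOVA calibration
uses 2000 null simulations at n = 50.

## Known limitations

* The five-iteration scheme assumes the landmark plane is within ~15° of
  the true axis; grossly misplaced landmarks can leave its capture basin.
  The per-iteration axes in the result object make divergence visible.
* The cylinder-source option `"contours"` fits a circular cylinder to a
  tapered, elliptical neck surface and can tilt several degrees relative to
  the centroid-based axis; centroids are the default for that reason.
* The algebraic sphere fit is exact on caps but not robust to gross
  outliers; robustness comes from the selection procedure, not the fit.
* STL stores float32; meshes survive round-trips watertight, but for
  lossless geometry tests PLY (written in full double precision) is the
  supported format.
* Binary PLY and non-triangular faces are not read.
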