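# fnaxis

Fitting the **femoral neck axis (FNA)** from a proximal-femur surface mesh
by the **centroid iterative method**, with the head-centre distance as its
accuracy metric and the reliability statistics used for repeated
measurements.

The FNA is the reference axis for femoral neck rotational osteotomy: the
femoral head is rotated about it, so an inaccurate axis concentrates stress
in the proximal femur. The axis is estimated from the bone surface alone:

1. the plane through the greater-trochanter tip, lesser-trochanter tip and
   the midpoint of the intertrochanteric line seeds the *initial section*;
2. 10 parallel sections 1 mm apart are cut toward the head; each closed
   mesh–plane contour's lamina centroid is computed by the shoelace
   formulas, `A = ½ Σ (xᵢ y₍ᵢ₊₁₎ − x₍ᵢ₊₁₎ yᵢ)`,
   `Cx = (1/6A) Σ (xᵢ + x₍ᵢ₊₁₎)(xᵢ y₍ᵢ₊₁₎ − x₍ᵢ₊₁₎ yᵢ)`;
3. a total-least-squares line is fitted through the centroid cloud and
   slicing repeats perpendicular to it — five iterations in total;
4. a cylinder is fitted to the final centroids; its axis is the FNA;
5. the femoral head is fitted as a sphere and **DBHF** — the distance
   between the sphere centre and the FNA — quantifies accuracy (the ideal
   head centre lies on the axis).

The package also provides a watertight **synthetic femur generator** with
exactly known axis, head centre and landmarks (implicit-surface union
meshed by marching tetrahedra), observer-noise simulation, **ICC(2,1)**
with F-based confidence intervals, and **two-way ANOVA** (Type II) for
gender × side comparisons.

## Worked example

```r
library(fnaxis)

fem <- generate_femur(femur_spec(voxel_pitch = 1.5))   # known ground truth
fit <- fit_fna(fem$mesh, fem$truth$landmarks)
fit
#> Centroid iterative FNA fit (5 iterations, 10 x 1.0 mm sections)
#> FNA: <line3> point (7.569, 2.028, 6.575)  direction (0.7399, 0.1983, 0.6428)
#> Head centre (40.29, 10.80, 35.00), radius 24.01 mm
#> DBHF: 0.002 mm

angle_between_lines(fit$fna, fem$truth$neck_axis)
#> [1] 0.0003256159
```

The fitted direction matches the constructed neck axis to about 0.0003° and
the head centre sits 0.002 mm from the fitted axis — on an ideal femur the
head centre lies on the axis, so DBHF near zero means both the axis and the
sphere fit are right. On real data DBHF of about a millimetre is expected
from true anatomical offset.

Real meshes are read with `read_mesh()` (STL binary/ASCII, PLY) and
landmarks with `read_landmarks()` (JSON); `run_fit()` wires files end to
end and writes a JSON report. A command-line wrapper is installed at
`system.file("cli", "fna", package = "fnaxis")` with subcommands `fit`,
`synth`, `eval`, and `stats icc` / `stats anova`.

Reliability statistics on a repeated-measurement table (rows = cases):

```r
st <- simulate_reliability_study(n_cases = 10, n_reps = 3, seed = 1)
icc(st$table)
#> ICC 1.000 (95% CI 1.000-1.000)
#>   two-way random, absolute agreement, single measure (ICC(2,1)); n = 10 subjects, k = 3 measurements
```

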