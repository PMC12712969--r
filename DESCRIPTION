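Package: fnaxis
Title: Femoral Neck Axis Fitting by the Centroid Iterative Method
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the femoral neck axis (FNA) of a proximal-femur surface
    mesh by the centroid iterative method: the plane through the greater
    trochanter tip, lesser trochanter tip and intertrochanteric-line
    midpoint seeds a stack of equally spaced cross-sections, each section's
    polygon centroid is computed, a total-least-squares line is fitted to
    the centroid cloud, and slicing is repeated perpendicular to the fitted
    line; a cylinder fit to the final centroids yields the axis. Accuracy is
    quantified as the distance between the sphere-fitted femoral head
    centre and the fitted axis (DBHF). Includes STL/PLY mesh input, a
    watertight synthetic proximal-femur generator with known ground truth
    for validation, observer-noise simulation, and the reliability
    statistics used for such measurements (intraclass correlation
    coefficients with confidence intervals and two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
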