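Package: enamelsim
Title: Diffusion-Limited Free-Boundary Simulation of Enamel Matrix Secretion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tooth enamel matrix secretion as a diffusion-limited
    moving-boundary (Stefan-type) process growing outward from an
    enamel-dentine-junction (EDJ) template. A nutrient field diffuses on the
    region exterior to the solid (dentine plus deposited matrix), is consumed
    at the advancing ameloblast front, and the front moves at a rate set by
    the local diffusive influx, regularized by a curvature-dependent
    (Gibbs-Thomson) interfacial tension. The interface is tracked with the
    level set method on a regular triangular mesh and the diffusion equation
    is solved by linear finite elements. Includes the excess-nutrient and
    geometric-extrapolation (fixed-radius dilation) null models, synthetic
    EDJ shape generators, virtual incremental-line recording, enamel
    area/perimeter and ridge-versus-valley thickness measurements,
    box-counting fractal dimension of binary contours, Hausdorff-type
    surface distance summaries, and 2D-slice-to-3D surface stacking.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
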