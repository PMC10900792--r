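Package: carotidflow
Title: Pulsatile Non-Newtonian Hemodynamics in a Carotid Bifurcation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation of pulsatile, incompressible,
    shear-thinning (Carreau) blood flow through an idealized carotid
    bifurcation. Provides a blood-case registry (anemic, diabetic, two
    healthy Carreau parameter sets), the piecewise systole/diastole inlet
    waveform of a 120 bpm cardiac cycle, parametric tube and planar
    Y-bifurcation geometries with structured staggered meshes, a
    projection-method finite-volume flow solver with Picard-lagged
    effective viscosity, analytic oracles (Poiseuille, power-law pipe
    flow, Womersley), wall shear stress, skin friction, strain rate and
    wall-deformation post-processing with cross-sectional plane
    statistics, grid-independence and time-step-sensitivity harnesses,
    and a comparative four-blood-case study pipeline with tertile
    high/average/low ranking tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
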