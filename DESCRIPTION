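Package: bioprintfidelity
Title: Quantitative Shape-Fidelity Assessment for Extrusion-Bioprinted Hydrogel Filaments and Grids
Version: 0.1.0
Authors@R:
    person("Mikail", "Osman", email = "mosman@example.org", role = c("aut", "cre"))
Description: Tools to quantify the shape fidelity of extrusion-bioprinted
    alginate/gelatin constructs. Implements a tensioned simply-supported
    Euler-Bernoulli beam model of filament collapse with closed-form and
    finite-difference solvers and inverse Young's-modulus estimation;
    image-based filament deformation metrics (deflection angles, diameter,
    time-to-flat, diameter-shrink slope); grid scaffold pore segmentation
    with normalized pore number and pore-area statistics; live/dead
    fluorescence viability quantification with an ImageJ-style find-maxima
    spot detector; single-factor ANOVA and paired t-test utilities; and
    seed-deterministic synthetic fixture generators (filament image series,
    grid images with controlled defects, two-channel z-stacks) so every
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
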