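Package: thoraxvar
Title: Population Variability and Rib Fracture Risk Sensitivity Analysis
    for Thorax Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how population variability in human thorax
    geometry and material properties propagates to occupant rib fracture
    risk. Provides a 15-parameter scaling model of rib and ribcage geometry
    (statistical shape modes, cortical thickness, cross-sectional width and
    height) and material properties (cortical and trabecular bone, costal
    cartilage, adipose and muscle tissue); a statistical shape model of rib
    centroidal curves with log-normal cortical thickness fitting; a
    probabilistic risk model for sustaining two or more fractured ribs
    (NFR2+) from per-rib peak strains; variance-based global sensitivity
    analysis (Sobol indices) via the multiplicative dimensional reduction
    method on a Gauss quadrature design, with a Monte Carlo oracle; a
    documented surrogate beam-bending thorax model standing in for
    finite-element crash simulation; and synthetic-data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
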