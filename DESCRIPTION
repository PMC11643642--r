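Package: tubuleflow
Title: Luminal Flow and Particle Transport in Actively Contracting Tubular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates low-Reynolds-number luminal flows and Brownian particle
    transport in planar networks of nanoscale tubules, such as the peripheral
    endoplasmic reticulum. Tubules undergo stochastic pinching with prescribed
    kinematics; the instantaneous flow field is obtained from a quasi-steady
    Kirchhoff (cycle-basis) solve of pinch-modified Hagen-Poiseuille relations,
    with optional wall slip. Alternative flow-generation mechanisms (contracting
    tubular junctions, perinuclear-sheet reservoirs, peripheral sheets) are
    included, along with closed-form transport bounds, Peclet and Reynolds
    estimates, membrane-bending force estimates, and energetic costs of sheet
    contractions. Provides a honeycomb network builder, a synthetic ER-like
    planar-network generator, a two-colour mixing experiment, and observables
    (instantaneous speeds, average edge traversal speeds, flow statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    fitdistrplus,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
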