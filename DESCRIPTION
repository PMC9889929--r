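Package: minicell
Title: Coarse-Grained Whole-Cell Model Building at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs molecular-resolution coarse-grained models of
    minimal bacterial cells: a circular chromosome grown as a self-avoiding
    lattice ring, relaxed as a twistable worm-like chain by Brownian
    dynamics and backmapped to base-pair resolution along
    rotation-minimizing frames; a crowded cytosol packed by rigid-body
    collision detection; a vesicle membrane realized from a triangulated
    surface with curvature-corrected leaflet compositions; and solvation
    in a rhombic dodecahedron box with neutralizing counterions and salt.
    Writes standard GRO coordinate files and composition reports, and
    scales from desk-size test cells to full cell geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
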