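Package: cellslice
Title: Inferring 3D Cell Shape Statistics from 2D Tissue Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stereological inference of three-dimensional cell shape from
    two-dimensional cross-sections of confluent tissue. Implements a periodic
    3D Voronoi model of cell packings with quadratic surface-area and volume
    penalties, FIRE energy minimization to generate packings at a target 3D
    shape index, exact plane-polyhedron slicing to build reference
    distributions of 2D shape descriptors (shape index and anisotropy), and a
    Kolmogorov-Smirnov fitting engine that estimates the mean 3D shape index
    (or inscribed-sphere fraction) from samples of 2D cell measurements, with
    quantified random and systematic errors under realistic measurement-noise
    models. Also measures 3D shape descriptors directly from labeled voxel
    volumes via an isosurface construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
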