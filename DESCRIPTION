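Package: phantomct
Title: Convert Tetrahedral-Mesh Computational Phantoms to DICOM CT and RT-Structure Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts tetrahedral-mesh (TM) computational human phantoms into a
    DICOM CT image series with a linked DICOM RT-structure set, for import into
    radiotherapy treatment-planning systems. Per-voxel mass densities are
    estimated by Monte-Carlo volume-fraction sampling of the tetrahedral
    partition, mapped to Hounsfield units through a piecewise-linear
    density-to-HU table, and written as a conformant CT series; organ boundary
    surfaces are extracted from the tetrahedra, sliced at the CT slice planes,
    and assembled into closed planar contours written as an RT-structure set
    sharing the CT frame of reference. Includes analytic-volume synthetic
    phantom generators (boxes, spheres, ellipsoids, deformable postures) for
    quantitative volume-preservation validation, a voxelization cache for fast
    reconversion, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
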