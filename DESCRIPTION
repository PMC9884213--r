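Package: crownforge
Title: Digital Workflows for Partial Dental Crown Design, Comparison and
    3D Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the three-phase digital workflow behind partial
    dental crown (inlay/onlay) restorations: quantitative comparison of
    3D surface scans (mesh surface area, enclosed volume, Hausdorff
    distance, signed surface deviation and Dice similarity on voxelized
    solids), computer-aided prosthesis synthesis by surface
    reconstruction and Boolean subtraction on voxel grids, and a
    17-layer 3D convolutional neural network that classifies voxelized
    tooth preparations as inlay or onlay with a frozen, proxy-pretrained
    feature block.  Includes a procedural tooth-anatomy simulator
    (intact crowns, mesio-occlusal-distal preparations, scanner noise
    models, five-fold oversampling and the 6-to-120 factorial study
    design), factorial ANOVA with cell summaries, pooled t-tests and
    noncentral-F power analysis.  Reads and writes both STL dialects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    car,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
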