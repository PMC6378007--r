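Package: fishfactory
Title: Simulation and Proximity Analysis of 3D-FISH Signals in Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying long-range spatial proximity of gene loci
    imaged by three-dimensional fluorescence in situ hybridization (3D-FISH).
    Includes an in-silico nucleus simulator (deformed-ellipsoid nuclei with
    nucleoli, procedural chromatin texture and diffraction-blurred point
    signals rendered into calibrated confocal-like z-stacks), nucleus
    segmentation and sub-voxel spot detection, pairwise 3D distance and
    colocalization statistics with a 2 micron long-range-interaction
    criterion, 14-interval distance distributions, nuclear volume
    comparisons, and a random-placement null model with a closed-form
    sphere-distance oracle for judging biological relevance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
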