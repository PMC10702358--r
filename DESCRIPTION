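Package: gelbead
Title: Droplet Microgel Bead Metrology, Encapsulation Statistics, and 3D
    Invasion Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis tools for droplet-microfluidic
    heterogeneous extracellular-matrix invasion assays. Detects, tracks
    and sizes hydrogel droplets in bright-field channel videos with a
    circular Hough transform and reports monodispersity; models
    cell-per-droplet occupancy with Poisson statistics including
    throughput and loading arithmetic; segments stained nuclei in
    anisotropic 3D confocal stacks (z interpolation, Otsu thresholding,
    Euclidean distance transform, marker-controlled watershed) and
    quantifies cancer-cell invasion out of a Matrigel bead (resident and
    invaded cell counts, maximum invasion distance) with group
    comparisons. Includes seeded synthetic-data generators with ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
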