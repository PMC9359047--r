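Package: anatmatch
Title: Knowledge-Based Radiotherapy Planning by Direct 3D Anatomy Match
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects anatomically similar patients from a radiotherapy plan
    database by FFT-accelerated translation-only registration of 3D binary
    planning-target-volume (PTV) masks, scores similarity with the Dice
    coefficient for the PTV and organs at risk, and transfers the achievable
    rectum and bladder V50Gy dose-volume constraints from the best-matched
    patients to a new patient. Includes contour rasterization onto voxel
    grids, cumulative dose-volume histogram metrics (VxGy, Dx, Dmax,
    homogeneity index) with plan-goal evaluation, paired cohort comparison,
    and a reproducible synthetic pelvic phantom cohort generator with a
    parametric dose-falloff model for end-to-end testing without clinical
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'anatmatch-package.R'
    'grid.R'
    'contours.R'
    'dvh.R'
    'registration.R'
    'similarity.R'
    'resample.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
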