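Package: tspoquant
Title: Quantification of TSPO PET with a Two-Tissue Compartment Model and
    Arterial Input Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute quantification of dynamic TSPO PET
    (e.g. [18F]-FEPPA) with a metabolite- and dispersion-corrected arterial
    plasma input function: blood curve merging and iterative dispersion
    deconvolution, bi-exponential blood-to-plasma and Hill parent-fraction
    models, reversible two-tissue compartment fitting with total distribution
    volume (VT), delta-method standard errors and a %COV quality filter, Logan
    graphical analysis for ROI and voxel-wise parametric VT images,
    Mueller-Gartner partial-volume correction, and genotype-by-disease cohort
    statistics (factorial ANCOVA with a nuisance covariate, Levene variance
    checks, stratified t tests, Pearson correlations). A synthetic-data module
    generates ground-truth input functions, time-activity curves, digital
    phantoms and genotype-stratified cohorts so that the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    car,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
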