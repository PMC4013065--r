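Package: phenorosette
Title: Top-Down Rosette Image Phenotyping and Shape-Descriptor Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantitative phenotyping of Arabidopsis rosettes
    from top-down photographs. Segments plants from background by
    nearest-neighbour colour classification with morphological cleanup and
    pot-region filtering, extracts twenty 2-D shape descriptors (areas,
    perimeters, convex-hull metrics, principal-axis statistics, moment of
    inertia) in physical units, computes relative rosette area growth rates
    between imaging dates, and runs the discrimination statistics used in
    longitudinal multi-ecotype experiments: log-transform policy,
    Bonferroni outlier screening, linear mixed-effects models with a random
    intercept per plant and AR(1) within-plant errors, pairwise contrasts
    with Bonferroni adjustment, per-time-point scaled PCA, and multi-class
    ReliefF feature ranking. Includes a synthetic rosette and
    descriptor-table generator with known ground truth so the whole
    pipeline is testable without original images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    igraph,
    jsonlite,
    png,
    jpeg,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
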