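Package: vestim
Title: Model-Based Vestibular Afferent Stimulation Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular workflow for simulating electrical stimulation of
    vestibular nerve branches in labeled tetrahedral models of inner-ear
    anatomy. Converts labeled voxel volumes to conforming tetrahedral meshes,
    computes nerve-fiber orientation fields from Laplace solves with Cauchy
    (Robin) boundary conditions, synthesizes nerve fibers as streamlines with
    nodes of Ranvier, places virtual electrodes, solves the quasistatic
    anisotropic Poisson equation for unit-current potential distributions,
    computes per-fiber activation thresholds with a myelinated-axon cable
    model, and evaluates recruitment curves, ROC/AUC selectivity, charge and
    energy metrics. Includes a seeded synthetic phantom anatomy generator so
    the whole pipeline is exercisable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    generics,
    Rcpp,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
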