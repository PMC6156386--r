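Package: warpstrain
Title: Biventricular Myocardial Strain from Cine MR by Hyperelastic Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of regional circumferential,
    longitudinal, and radial Green-Lagrange strain in a biventricular
    finite-element model registered to short-axis cine image stacks by
    hyperelastic warping: a Neo-Hookean regularized, intensity-driven
    deformable registration with a prescribed sinusoidal basal longitudinal
    excursion. Includes a synthetic biventricular phantom with analytic
    ground-truth motion, Laplace-Dirichlet rule-based local direction
    fields, region partitioning of the wall into left-ventricular free
    wall, septum and right-ventricular free wall, strain-time curve
    extraction with end-diastolic reference remapping, and a
    reproducibility and discrimination statistics layer (Bland-Altman,
    coefficient of variation, intraclass correlation, ROC with Youden
    cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
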