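Package: ovhplan
Title: Overlap-Volume-Histogram Guided Dose-Constraint Prediction for Breast Radiotherapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for knowledge-based radiotherapy treatment planning built on
    the overlap volume histogram (OVH). Computes signed Euclidean distance
    fields on anisotropic voxel grids, OVH curves between a planning target
    volume and organs at risk, cumulative dose-volume histograms and plan
    quality metrics (D_x, V_d, mean dose, conformity and homogeneity indices),
    fits and applies per-cohort linear models linking OVH geometry (L_x, mm) to
    achievable dose levels (D_x, Gy), converts predictions into optimization
    constraint templates, and generates seeded synthetic thorax phantoms with
    analytically known geometry-dose laws for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
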