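Package: afstress
Title: Simulation Stress Tests of Left Atrial Substrates for Predicting
    Atrial Fibrillation Ablation Outcome
Version: 0.1.0
Authors@R: person("Maintainer", "afstress", email = "afstress@example.org",
    role = c("aut", "cre"))
Description: A virtual-cohort pipeline for studying long-term outcome after
    pulmonary vein isolation (PVI) in atrial fibrillation (AF). Generates
    synthetic left-atrial surface meshes with pulmonary-vein ostia, fibrosis
    fields parameterised by the image intensity ratio (IIR), and rule-based
    fiber maps; runs monodomain reaction-diffusion simulations with a
    phenomenological atrial cell model; applies an 11-setup model-variant
    stress battery (fibrosis type, fiber map, PVI lesion size, AF initiation
    map, effective refractory period); extracts phase-singularity and
    dominant-frequency metrics plus imaging-area metrics into a per-patient
    signature; and trains cross-validated classifiers (KNN, SVM, random
    forest, logistic regression, with optional PCA) to predict one-year AF
    recurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    methods,
    stats,
    utils,
    FNN,
    digest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
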