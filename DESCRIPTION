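Package: capdyn
Title: Co-Activation Pattern Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("CAPdyn", "Developers", email = "capdyn@example.org",
    role = c("aut", "cre"))
Description: Extraction and statistical analysis of co-activation patterns
    (CAPs) from resting-state fMRI: frame-wise K-means++ clustering under
    correlation distance with elbow-based model selection, spatial and
    temporal CAP statistics (one-sample T maps, voxel-wise two-way ANOVA
    with FDR and in-plane cluster-extent correction, occurrence and
    duration metrics with repeated-measures ANOVA), leakage-controlled
    genotype classification with permutation chance baselines, and
    surrogate-based inference on inter-CAP transition probabilities and
    their directionality. Includes a synthetic-cohort generator with known
    Markov state sequences and planted group effects so the full pipeline
    is testable end to end, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
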