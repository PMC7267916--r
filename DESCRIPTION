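Package: taskpred
Title: Predicting Individual Task Activation Maps from Resting-State Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual task-fMRI activation (z-score) maps from
    resting-state functional-connectivity features. Implements the full
    pipeline: group PCA and per-hemisphere spatial ICA with left-right
    symmetry filtering, dual regression to subject-level network maps,
    correlation feature maps with subcortical parcels, random geodesic
    Voronoi parcellation of the cortical surface, and three per-parcel
    regression families (pseudoinverse GLM, Rprop-trained feed-forward
    neural networks, and random-forest bagging) combined by ensemble
    averaging. Includes a synthetic multi-subject cohort generator with
    known ground truth, sequential one-parameter-at-a-time hyperparameter
    search, and evaluation via cross-subject correlation matrices,
    Gaussian-gamma mixture-model thresholding with Dice overlap, and
    repeated-measures ANOVA model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
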