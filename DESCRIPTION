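Package: fcparcel
Title: Seed-Based Functional Connectivity and Fuzzy Parcellation for
    Resting-State BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectivity
    analysis of a cortical target region: temporal detrending and band-pass
    filtering, Gaussian spatial smoothing, seed-ROI general linear models
    with orthogonalized regressors, tissue/global/motion nuisance control
    and AR(1) prewhitening, Monte-Carlo cluster-extent correction,
    random-effects group maps and probability maps, voxelwise fuzzy c-means
    parcellation with PCA reduction and unsupervised cluster-count
    selection, cross-subject cluster matching, and split-half
    Spearman-Brown reliability with Sorensen-Dice overlap. Includes a
    synthetic multi-subject BOLD cohort generator with planted network
    structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
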