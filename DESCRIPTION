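Package: dfcvar
Title: Seed-Based Dynamic Functional Connectivity Variance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window, seed-to-voxel dynamic functional connectivity
    (dFC) analysis for resting-state fMRI, built around insular subdivision
    seeds. Computes per-voxel variability (standard deviation over Hamming-
    tapered windows of Fisher-z correlations), performs voxelwise two-sample
    inference with Gaussian-random-field cluster-level correction,
    brain-behavior Pearson correlation with Benjamini-Hochberg FDR, and
    leave-one-out cross-validated linear SVM classification with permutation
    testing. Includes a synthetic two-group BOLD cohort generator with known
    injected group differences in dynamic coupling, plus the functional
    preprocessing chain (volume discard, nuisance regression, ideal bandpass,
    Gaussian smoothing) and motion quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
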