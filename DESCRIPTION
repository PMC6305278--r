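Package: gsradiomics
Title: Radiomic Texture Analysis for Gleason Score Group Prediction from mpMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end radiomic analysis of paired T2-weighted and apparent
    diffusion coefficient (ADC) prostate MRI volumes for discriminating
    Gleason-score groups. Extracts 41 intensity and texture features (histogram,
    gray-level co-occurrence matrix, neighborhood gray-tone difference matrix,
    gray-level size-zone matrix) from lesion-centred 21x21x3 sub-volumes
    quantized to 32 gray levels, screens features with Kruskal-Wallis tests and
    Spearman rank correlations under Holm-Bonferroni correction, and classifies
    groups with one-vs-rest random forests (cross-validated and held-out), with
    normalized out-of-bag permutation importance. Includes a synthetic cohort
    generator with group-dependent zone-size texture for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
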