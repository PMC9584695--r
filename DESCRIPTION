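Package: dcpredict
Title: Voxelwise Degree Centrality and Treatment-Response Prediction for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for graph-based analysis of resting-state BOLD fMRI:
    temporal preprocessing (volume discard, frame-wise displacement and
    motion exclusion, Friston-24 plus global-signal nuisance regression,
    band-pass filtering), voxelwise degree-centrality maps from thresholded
    Pearson correlation graphs with z-scoring and Gaussian smoothing,
    covariate-adjusted voxelwise group inference with Benjamini-Hochberg
    false-discovery-rate control, linear support-vector-machine
    leave-one-out classification of antipsychotic treatment response with
    permutation significance and discriminative weight maps, and
    correlation of centrality change with symptom change. Includes a
    synthetic-cohort generator with latent-network structure and planted
    hub effects so the full pipeline can be exercised and calibrated
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
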