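Package: gonogoCa
Title: Population Analysis of Calcium Imaging in a Sound-Detection Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium-imaging recordings
    acquired while head-fixed mice perform a go/no-go click-detection task.
    Provides a synthetic session simulator with full ground truth
    (truncated-normal trial schedules, psychometric behaviour, calcium-kernel
    neural traces), fluorescence conditioning (neuropil correction, median-F0
    dF/F, slow-baseline removal, trial-tensor extraction), behavioural scoring
    and psychometrics (d-prime), per-neuron outcome-modulation and
    sound-response statistics with Benjamini-Hochberg correction, spectral
    clustering of trial-averaged hit/miss response profiles with
    silhouette-based model selection, and frame-by-frame population decoding of
    trial outcome using class-weighted L2 logistic regression under nested
    stratified cross-validation, scored by balanced accuracy against stratified
    dummy baselines, with timewise group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    glmnet,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
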