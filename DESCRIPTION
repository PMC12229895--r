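Package: driftmap
Title: Longitudinal Representational-Map Analysis for Targeted
    Microablation Calcium-Imaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal two-photon calcium-imaging
    studies of the mouse auditory cortex with targeted single-neuron
    microablation. Converts raw fluorescence traces or trial-resolved
    response tensors into per-neuron responsiveness classifications
    (exact Wilcoxon signed-rank with Benjamini-Hochberg correction),
    single-neuron tuning statistics (split-half reliability, tuning
    width, signal correlations), stimulus-pair representational
    similarity matrices with classical MDS embeddings and pairwise SVM
    decoding, microablation target selection and spared-network
    exclusion masks, and the permutation, field-of-view shuffle and
    tuning-width scaling procedures used to attribute map disturbance
    and recovery to single-neuron changes. Includes a synthetic cohort
    generator with ground-truth export for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
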