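Package: dtcwtcad
Title: Dual-Tree Complex Wavelet Features for Binary Classification of
    Brain MR Slice Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for two-class
    classification of multi-slice 2-D brain magnetic resonance images.
    Implements a from-scratch 2-D dual-tree complex wavelet transform
    (DTCWT) with six directionally selective complex subbands per level
    and near shift invariance, per-subject texture feature extraction
    from coarse-scale subband coefficients, principal-component score
    reduction with variance-threshold component selection, a two-layer
    feed-forward neural network trained by scaled conjugate gradient
    with optional class-cost weighting for unbalanced cohorts, repeated
    stratified k-fold cross-validation with confusion-matrix metrics,
    and a seeded synthetic cohort generator so that the whole pipeline
    is testable without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
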