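Package: stlrnet
Title: Group-Similarity Constrained Functional Brain Network Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of functional brain networks from multi-subject ROI
    time series under a group-similarity prior. Implements sparse plus tensor
    low-rank (STLR) regression solved by proximal gradient descent with
    CP/PARAFAC-based trace-norm shrinkage, together with baseline estimators
    (Pearson correlation with thresholding, sparse representation, sparse
    low-rank, group-sparse, and tensor low-rank regression), a two-class
    connectome classification pipeline (t-test feature filtering, linear SVM,
    nested leave-one-out cross-validation), global graph-theory
    characterization with degree-preserving null models, and a synthetic
    cohort generator with known ground-truth networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
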