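Package: pdskit
Title: Pathway-Derived Subtyping of Colorectal Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("PDS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for pathway-level tumor subtyping of bulk and single-cell
    expression matrices. Implements single-sample gene-set enrichment (ssGSEA)
    and kernel-CDF (GSVA) scoring, unsupervised pathway-level class discovery
    (t-SNE embedding, scaled k-means, silhouette/elbow/bootstrap-stability k
    selection), subtype-specific feature selection with correlation pruning, a
    probability-thresholded RBF-SVM classifier with a "mixed" category and
    reference-batch ComBat alignment, derived transcriptomic indices (stem
    maturation index, proliferative index, replication stress, stem-signature
    scores, tertile high/low labels), and a synthetic cohort generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    cluster,
    Rtsne,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
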