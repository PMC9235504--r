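Package: jointCCA
Title: Multimodal Single-Cell Integration by Canonical Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a shared low-dimensional representation of cells measured
    across two or more single-cell modalities (RNA, surface protein, chromatin
    accessibility) profiled on the same cells. Each modality is first reduced
    independently (PCA for RNA/protein, TF-IDF plus LSI for ATAC); pairs of
    reduced embeddings are then aligned by canonical correlation analysis
    solved through a generalized eigendecomposition, noisy components are
    removed with a correlation t-test and Benjamini-Hochberg control, and
    additional modalities are folded in sequentially. Canonical components can
    be traced back to the original molecular features for interpretation, and
    the resulting latent space can be scored against reference labels with
    structure-preservation, silhouette and Louvain/ARI metrics. A seeded
    simulator of multimodal count data with known population structure
    supports testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    irlba,
    RANN,
    igraph,
    mclust,
    cluster,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
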