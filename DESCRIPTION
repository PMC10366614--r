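Package: manifoldFC
Title: Manifold Learning for Time-Varying Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and low-dimensional embedding of sliding-window
    time-varying functional connectivity (tvFC) matrices from ROI timeseries.
    Implements Laplacian Eigenmaps, T-SNE and UMAP from their defining
    equations, global and local intrinsic-dimension estimation (twoNN, local
    PCA), connectivity- and phase-randomization null models, silhouette and
    predictive (logistic regression) evaluation frameworks, two group-level
    aggregation strategies (concatenation and Procrustes alignment), and a
    seeded synthetic multi-task fMRI generator with task-specific covariance
    states, temporal autocorrelation and subject connectome fingerprints.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    glmnet,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
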