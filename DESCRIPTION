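Package: diffproj
Title: Adaptive Diffusion Embedding, Clustering and Trajectory Analysis for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Dimensionality reduction of single-cell RNA-seq data by adaptive
    anisotropic diffusion maps with multiscale component weighting and eigengap
    component selection, followed by a UMAP-style two- or three-dimensional
    layout of the selected structure components. Includes the surrounding
    workflow: quality-control filtering with knee detection, log-normalization,
    highly-variable-gene selection and scaling; shared-nearest-neighbor
    modularity clustering with one-vs-rest marker ranking and dot-plot
    statistics; cell-cycle module scoring; absorbing-Markov-chain pseudotime,
    branch probabilities and differentiation entropy with diffusion imputation
    and gene trends; and negative-binomial simulators of clustered, cyclic and
    branching single-cell data with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    RSpectra,
    RANN,
    uwot,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
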