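Package: scTransit
Title: Transition-State Analysis of Single-Cell RNA and ATAC Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dissecting progenitor transition states
    from single-cell transcriptomes and chromatin accessibility. Covers
    MAD-based cell and gene quality control, pooled ring-deconvolution size
    factors, windowed mean-stratified selection of heterogeneous genes,
    self-organizing-map metagene reduction with t-SNE/HDBSCAN clustering,
    AUROC marker ranking, the critical transition index with bootstrap,
    pairwise cell-to-cell distance distributions, diffusion-map pseudotime
    with projection of perturbed cells, pseudotime-correlated gene dynamics,
    cell-cycle scoring with correlation refinement, a rule-based smooth-muscle
    classifier, and a scATAC arm (TF-IDF/SVD embedding, cluster-specific
    peaks, motif accessibility deviation Z-scores, RNA:ATAC trend pairing).
    Ships ground-truthed synthetic-data generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Rtsne,
    irlba,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    scran,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
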