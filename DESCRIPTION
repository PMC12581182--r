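Package: flowSDC
Title: Signed Distance Correlation Analysis of Lymphoma Tumor
    Microenvironments from Spectral Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An unsupervised analysis pipeline for high-dimensional
    (spectral) flow cytometry of lymphoma tumor microenvironments:
    logicle transformation and acquisition-anomaly quality control,
    self-organising-map clustering with consensus metaclustering and
    elbow-guided cluster number selection, marker enrichment modelling
    (MEM) annotation, F1-driven automatic gating with per-marker
    importance, per-sample metacluster frequency statistics
    (Mann-Whitney, Kruskal-Wallis with Dunn's post hoc,
    Benjamini-Hochberg correction, PCA), and inference of
    ligand-receptor cell-cell communication by signed distance
    correlation of median fluorescence intensities across samples with
    permutation p-values. Includes a synthetic cohort generator with
    known ground truth (group-dependent metacluster abundances, latent
    ligand-receptor couplings, doublets, dead cells and acquisition-time
    anomalies) and FCS 3.0 / CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
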