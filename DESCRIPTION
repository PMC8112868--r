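Package: cytosuite
Title: Import, Clustering and Differential Analysis of Mass and Flow
    Cytometry Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@cytosuite.dev",
           role = c("aut", "cre"))
Description: A scriptable three-stage framework for liquid mass cytometry
    (CyTOF), imaging mass cytometry (IMC) and fluorescence flow cytometry
    single-cell marker-expression data: (1) FCS/CSV import, arcsinh
    transformation, adaptive downsampling and sample-level quality control
    (median MDS, annotated heatmaps); (2) UMAP/tSNE embeddings and
    unsupervised clustering by a SOM + consensus-metaclustering ensemble,
    kNN-graph (PhenoGraph-style) community detection, or k-means, with
    labels stored for every K and consensus elbow diagnostics; (3)
    reproducible table-driven cluster annotation, ranked-expression
    heatmaps for IMC, differential cluster abundance and differential
    marker expression testing with Benjamini-Hochberg FDR control. Ships a
    seeded synthetic-data generator with known population structure and
    group effects, an HDF5 container for all analysis layers, and a
    subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    igraph,
    FNN,
    uwot,
    Rtsne,
    rhdf5,
    jsonlite,
    yaml,
    ggplot2,
    pheatmap,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
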