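Package: fibrosig
Title: Fibrosis Gene Signatures and Cardiac Fibroblast Subpopulation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving a compact fibrosis gene signature from
    targeted expression panels of heart-failure cohorts (reference-gene
    normalization, age correction, projection-score subset selection,
    patient subclustering), for resolving cultured cardiac-fibroblast
    subpopulations from single-cell spliced/unspliced counts (QC, doublet
    scoring, Louvain clustering, marker detection, steady-state RNA
    velocity), for matching patient signatures to fibroblast subpopulations
    by correlation, and for staging bulk infarct time courses with
    subpopulation marker sets. Includes synthetic-data generators with known
    ground truth for all three data kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment, SingleCellExperiment
Imports: methods, stats, utils, Matrix, S4Vectors, BiocNeighbors, igraph,
    cluster, irlba, mclust, yaml
Suggests: testthat (>= 3.0.0), withr, uwot
Config/testthat/edition: 3
biocViews: GeneExpression, SingleCell, RNASeq, Clustering, Software
RoxygenNote: 7.3.3
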