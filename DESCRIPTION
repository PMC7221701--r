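Package: qsarfunnel
Title: QSAR Model Building and Multitarget Virtual-Screening Funnel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for ligand-based QSAR modeling and multitarget
    virtual screening of small molecules. Provides a molecular graph data
    model with SMILES and SDF input, topological / constitutional /
    charge-related / surface-area (CPSA) descriptor computation with
    ingestion of external quantum-chemical descriptor columns, best
    multilinear regression (BMLR) forward descriptor selection with
    leave-one-out and interleaved three-fold (ABC) cross-validation and
    X/Y/XY-scrambling randomization tests, a backpropagation neural
    network model builder with stepwise input selection (BeANN), and a
    screening funnel combining ligand-efficiency, Lipinski, solubility
    and applicability-domain filters with linear/neural consensus
    predictions of log10 IC50. Seeded synthetic-data generators with
    known ground truth support end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
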