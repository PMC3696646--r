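Package: ecmProfiler
Title: Comparative Spectral-Count Proteomics of Cell-Derived
    Extracellular Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free comparative proteomics of cell-derived
    extracellular matrix (ECM) preparations. Implements identification
    filtering with decoy-based protein FDR estimation, normalized
    spectrum-count quantification with replicate averaging,
    extracellular/cell-surface classification from Gene Ontology
    annotations, multi-sample overlap statistics, hierarchical
    clustering of abundance profiles with uncentered Pearson
    correlation and per-cluster hypergeometric enrichment
    (Benjamini-Hochberg corrected), merged protein-protein interaction
    network topology, and supportive-versus-unsupportive differential
    comparison with candidate-substrate ranking. Ships a fixture of a
    published ECM abundance table and a seeded synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
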