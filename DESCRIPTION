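Package: hyperricci
Title: Forman-Ricci Curvature on Higher-Order Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models protein-protein interaction networks as 2-dimensional
    simplicial complexes in which triangles of interacting proteins
    (feedforward or feedback loops in the directed case) are promoted to
    faces. Gene-expression values weight the complex through mass-action
    interaction probabilities, a Markov random walk and a resistance
    quasimetric, and Forman-Ricci curvature is computed on the weighted
    complex in both its 1-dimensional (graph) and 2-dimensional
    (hypergraph) forms, together with the walk's entropy rate. Includes
    topology summaries (Euler characteristic, degree distributions,
    power-law fits, Erdos-Renyi comparison), per-gene differential
    curvature statistics with FDR control, ROC/AUC with DeLong
    comparison, hypergeometric gene-set overrepresentation, and seeded
    synthetic-data generators for networks and two-group expression
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    data.table,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    fgsea,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
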