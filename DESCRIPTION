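Package: comolead
Title: Comorbidity-Driven Gene Refinement, Network Modules, and ADME-Guided
    Dual-Kinase Lead Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for comorbidity-driven drug discovery:
    aggregation and refinement of disease gene panels, protein-association
    network statistics and MCODE module detection, co-expression partner
    analysis, hypergeometric over-representation with Benjamini-Hochberg
    correction, scaffold hybridization on molecular graphs with linker-based
    merging, docking-score table analytics (best binders, binding-energy
    improvements, dual-target summaries), a local ADME rule engine (Lipinski,
    Ghose, Veber, Egan and Muegge filters, ESOL solubility, Abbott
    bioavailability score, structural alerts, liability classification), and
    multi-criteria lead selection with retention banding and a weighted
    composite score. A synthetic-data module generates gene panels with exact
    overlap structure, planted-module graphs, block-correlated expression
    matrices, and alert-bearing toy compounds so that every stage runs and is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    igraph,
    stats,
    utils,
    withr,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
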