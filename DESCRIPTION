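Package: repograph
Title: Data-Driven Drug Repositioning on a Typed Semantic Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous gene-disease evidence by Bayesian
    log-likelihood scoring with weighted-sum combination, builds a typed
    semantic drug-discovery graph (drugs, proteins, genes, common and rare
    diseases), prioritises therapeutic areas by unmet-need and data-richness
    scores, computes a path-based MeSH semantic similarity, exhaustively
    mines the drug-protein-gene-disease semantic subgraph to infer candidate
    drug-disease indications, prunes them through side-effect,
    mechanism-directionality and ADME-gene filters, and validates inferred
    indications against known ones by similarity-tolerant recall and ROC
    analysis. Includes a deterministic synthetic-fixture generator with
    planted repositioning opportunities so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
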