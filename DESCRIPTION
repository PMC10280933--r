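Package: cernascope
Title: Co-Dysregulated lncRNA-miRNA-mRNA (ceRNA) Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end inference of co-dysregulated competing-endogenous-RNA
    (ceRNA) networks from two-group expression profiling: Welch differential
    expression with fold-change gates, Pearson co-expression screening of
    lncRNA-mRNA pairs, shared-miRNA triple assembly into a tripartite
    lncRNA-miRNA-mRNA network, degree-based hub extraction, MCODE-style dense
    module detection on protein-protein interaction graphs, hypergeometric
    over-representation and GSEA enrichment statistics, and 2^-ddCt qPCR
    validation statistics. Includes a seeded synthetic-data generator that
    plants every structure the analysis assumes (differential genes,
    near-perfect co-expressed pairs, ceRNA triples, a hub lncRNA, a dense PPI
    clique) together with its ground truth, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
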