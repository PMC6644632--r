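Package: termnet
Title: Pooled Gene Set Enrichment and Interaction Network Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-centric knowledge integration for interpreting gene lists
    from high-throughput studies. Reads gene set resources (GMT) and
    interaction networks (edge lists, SIF), performs pooled hypergeometric
    over-representation analysis across multiple resources with a single
    false-discovery correction, quantifies shared-gene overlap between terms
    and reduces a union of resources to a minimally redundant set, expands
    query gene sets through interaction networks by neighbor or connector
    genes, and renders study-design-annotated enrichment heatmaps with
    Cytoscape-ready exports. Includes a seeded synthetic-fixture generator
    with exactly constructed overlap structure and planted enrichment signal
    so every analysis is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
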