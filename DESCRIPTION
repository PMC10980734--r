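Package: orthoppi
Title: Cross-Species Protein Interaction Network Analysis and Key
    Regulator Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative network analysis of disease-associated
    genes across species. Screens differentially expressed genes from
    two-group log2 expression matrices, builds cleaned protein-protein
    interaction (PPI) networks from scored edge tables, computes node
    centralities (degree, Brandes betweenness, closeness, bottleneck) and
    degree-indexed topology profiles, intersects top-ranked lists to
    identify key-regulator genes, projects gene sets into a model organism
    through ortholog tables, detects dense network modules with an MCODE
    implementation, performs hypergeometric gene-set over-representation
    analysis with Benjamini-Hochberg correction, and compares enriched
    terms between species. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
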