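Package: phytonet
Title: Integrative Network-Pharmacology Screening for Multi-Component Herbal Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative network-pharmacology pipeline for nominating the
    key chemical components and hub protein targets of a multi-component
    herbal extract against a disease phenotype. Ingests tables of identified
    chemical components with mass-spectrometry response values, similarity-scored
    compound-target predictions, multi-source disease-gene records, gene-set
    annotations (GMT), literature-evidence counts and docking affinities;
    intersects the drug-target and disease-gene spaces, performs hypergeometric
    over-representation analysis, builds the tripartite compound-target-pathway
    network with degree, closeness and betweenness centralities, screens hub
    targets by the median-degree rule and key components by a two-of-three
    multi-evidence rule (network topology, literature mining, quantitative
    MS response), and applies a docking-affinity threshold screen. Includes a
    seeded synthetic-evidence generator with planted hubs for benchmarking
    recovery, and network export in GraphML and SIF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
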