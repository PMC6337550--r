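Package: herbnet
Title: Network Pharmacology of Multi-Herb Formulas by ADME Screening and
    Topological Hub Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-pharmacology pipeline linking a multi-herb formula to
    candidate protein targets and pathways. Compounds are screened by five
    ADME criteria (oral bioavailability, drug-likeness, Caco-2 permeability,
    blood-brain-barrier penetration, half-life) with a literature-rescue
    whitelist; compound-target bipartite networks are built and intersected
    with disease gene lists; seed-expanded protein-protein-interaction
    networks are merged into a core network; hubs are screened by six
    topological features (degree, betweenness, closeness, eigenvector,
    network centrality, local average connectivity) against their medians;
    and candidate targets are tested for term enrichment with kappa-statistic
    term grouping. A synthetic-data generator with planted ground truth
    replaces live compound and interactome databases so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
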