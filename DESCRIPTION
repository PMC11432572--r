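Package: agenet
Title: Topology Analysis of Curated Molecular Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds undirected molecular interaction networks from curated
    databases (multi-sheet workbooks, edge lists, SIF), computes the standard
    node-level topological metric suite (degree, clustering coefficient,
    betweenness and closeness centrality with explicit normalization, stress,
    eccentricity, radiality, neighborhood connectivity, topological
    coefficient), classifies networks as Barabasi-Albert scale-free via a
    log-log least-squares power-law fit of the degree distribution together
    with a degree-clustering independence check, identifies hub nodes
    (degree above mean plus one standard deviation) and bottleneck nodes
    (shortest-path-tree scoring), and flags outlier nodes by principal
    component analysis of the metric matrix with a confidence-ellipse
    criterion. Includes deterministic synthetic-network generators emulating
    a curated AGE-fertility-immunity interaction network so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    readxl,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
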