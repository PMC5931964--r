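Package: anatnet
Title: Anatomical Network Analysis of Limb Musculoskeletal Organization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for anatomical network analysis (AnNA) of musculoskeletal
    systems. Builds simple undirected networks of bones, cartilages and
    muscles from labelled 0/1 adjacency matrices; computes the six
    topological descriptors (node and link counts, density of connections,
    mean local clustering, characteristic path length and degree
    heterogeneity) used as proxies for anatomical complexity, integration
    and anisomerism; detects connectivity modules with an agglomerative
    short-random-walk algorithm scored by Newman-Girvan modularity with
    jackknife standard errors and per-module one-sided rank-sum tests; and
    quantifies similarity between networks with the average relative
    difference (ARD) of their parameters. A generator of synthetic
    limb-like musculoskeletal networks with planted modular structure
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'network.R'
    'io.R'
    'parameters.R'
    'walktrap.R'
    'modularity.R'
    'comparison.R'
    'synthetic.R'
    'pipeline.R'
    'anatnet-package.R'
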