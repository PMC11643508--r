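Package: simpliciality
Title: Measuring the Simpliciality of Higher-Order Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how close a hypergraph is to satisfying downward
    closure, i.e. to being a simplicial complex. Provides three global
    measures (the simplicial fraction, the edit simpliciality, and the face
    edit simpliciality) together with edit-distance variants, size-restricted
    power sets with configurable minimal-face handling, local (nodal)
    simpliciality on ego-hypergraphs, simplicial assortativity on the
    pairwise projection, and randomized baselines (a degree- and
    size-preserving configuration model via bipartite double edge swaps and
    a bipartite Chung-Lu sampler). Includes readers and writers for
    hyperedge-list, bipartite incidence, and JSON hypergraph formats, a
    planted-inclusion synthetic generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
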