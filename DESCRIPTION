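Package: diverseclub
Title: Diverse-Club and Rich-Club Analysis of Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying network hubs by strength (the rich club)
    versus participation coefficient (the diverse club), quantifying how
    interconnected each club is relative to degree-preserving randomized
    null ensembles, simulating lesions to intra-club edges and measuring
    the resulting loss of global efficiency, and running a generative
    evolutionary model in which edge rewiring is selected to jointly
    maximize modularity and efficiency. Includes a uniform interface to
    nine community-detection algorithms, cost-based graph thresholding
    with maximum-spanning-tree retention, and synthetic fixture
    generators (planted partitions with designed bridge nodes,
    Erdos-Renyi graphs, ring lattices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
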