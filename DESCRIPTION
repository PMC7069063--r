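Package: asntopo
Title: Topological Analysis of Self-Assembled Nanowire Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-assembled nanowire networks as random 1D segments
    deposited on a 2D plane, extracts the wire-junction graph (nodes are
    nanowires, edges are wire-wire intersections), and characterises its
    topology with the standard complex-network battery: mean path length,
    local clustering, small-world propensity against lattice and
    density-matched random nulls, modularity partitioning, participation
    coefficient, within-module degree z-score, and cartographic node
    classification. Also constructs the reference families these networks
    are compared against: Watts-Strogatz rewiring sweeps, fully-connected
    layered artificial neural network graphs, and connectome edge lists,
    with an ensemble pipeline that aggregates per-network summaries and
    runs one-way ANOVA group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
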