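Package: connectogen
Title: Generative Network Models for Spatially Embedded Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for growing, fitting, and stress-testing generative network
    models (GNMs) of spatially embedded brain networks. Networks are grown
    edge-by-edge under cost-versus-feature wiring rules (exponential or
    power-law distance penalty, optionally combined with a static interregional
    similarity matrix or the dynamically updated matching index). Model
    parameters are fitted with a Voronoi-tessellation preferential resampling
    scheme that minimises the maximum Kolmogorov-Smirnov statistic across the
    degree, clustering, betweenness, and connection-length distributions.
    Includes a synthetic-data generator for spatially embedded target networks
    with planted long-range hub edges and spatially autocorrelated nodal
    features, length-aware rewiring null models, and distance-resolved
    diagnostics (distance-binned connection recovery, thresholded-degree
    profiles, probability-versus-distance tables, and sliding-window
    precision curves).
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
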