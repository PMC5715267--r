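Package: mcpcluster
Title: Shape-Invariant Clustering and Mapping of Expression Profiles via
    Multiple-Cumulative Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters and visualizes gene expression time courses using the
    multiple-cumulative probability (MCP) transform. Each profile is normalized
    to a discrete probability vector, cyclically permuted, and expanded into a
    concatenation of modified cumulative sums; Pearson correlation or Euclidean
    distance between MCP vectors (PCC-MCP, ED-MCP) then measures similarity of
    expression behaviour robustly to curve-shape noise. Provides the icc-cluster
    k-medoid algorithm with farthest-first seeding, a k-means baseline,
    silhouette-selected t-SNE maps of principal-component-truncated MCPs,
    gene nearest-neighbor overlays, a simulator for benchmark data, and a
    file-based pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
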