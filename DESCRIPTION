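Package: mstClust
Title: Spanning-Tree Brain Network Similarity and Spectral Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds spanning-tree functional brain networks from regional
    BOLD time series (Pearson correlation followed by descending-weight
    Kruskal reduction), measures pairwise network similarity as a
    delta-weighted fusion of a betweenness-based cosine attribute
    similarity and a multi-level sub-network kernel built on Krylov
    covariance descriptors, clusters subjects by normalized spectral
    clustering, and evaluates clustering consistency against diagnostic
    labels. Includes a synthetic cohort generator with planted group
    topology for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, MASS
Suggests: testthat (>= 3.0.0), igraph, withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
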