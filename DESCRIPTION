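Package: cernaNet
Title: Bipartite miRNA-mRNA Targeting Networks and Gene Co-Targeting Projections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds validated bipartite gene-miRNA targeting networks from
    comma-delimited adjacency lists of experimentally supported interactions,
    computes degree and frequency distributions for both node classes,
    projects the bipartite graph onto the gene set with integer edge weights
    counting shared targeting miRNAs, computes betweenness centrality of the
    projected co-targeting network (Brandes' algorithm, unweighted or
    inverse-weight distances), ranks and extracts highly co-targeted
    subnetworks of candidate competing endogenous RNAs (ceRNAs), and exports
    styled graphs (vertex size from centrality, edge width and transparency
    from shared-miRNA counts) as edge-list CSV and GraphML. Includes a seeded
    synthetic adjacency-list generator with a planted co-targeting motif for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Matrix, igraph
Suggests: testthat (>= 3.0.0), xml2, optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
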