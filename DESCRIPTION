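Package: pandanet
Title: Co-Occurrence Network Analysis of Gut Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses microbial co-occurrence networks from OTU
    count tables, following the workflow used in comparative gut-microbiome
    studies of captive and wild giant panda populations: selection of the
    most abundant OTUs per group, pairwise Spearman correlation with
    significance filtering, signed network construction, node centralities,
    Newman modularity and module detection, within-module (Zi) and
    among-module (Pi) connectivity with node-role classification, keystone
    and rare/abundant taxa partitioning, and edge-based dissimilarity
    between networks. Includes a seeded synthetic OTU-table generator with
    planted modular correlation structure so that every stage of the
    pipeline can be exercised and validated without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
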