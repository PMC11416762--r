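Package: ppirank
Title: Neighborhood-Similarity Gene Prioritization on Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("ppirank", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Guilt-by-association gene prioritization on protein-protein
    interaction (PPI) networks. Computes neighborhood Jaccard and
    Sorensen-Dice similarity for every gene pair sharing at least one
    neighbor, integrates them into a sparse similarity matrix, scores and
    ranks genes by their summed similarity to a seed gene set, tests
    gene-pathway association with a permutation null over random gene
    sets, and performs minimal hypergeometric over-representation
    analysis with Benjamini-Hochberg adjustment. Includes a
    planted-module synthetic network generator so the whole pipeline is
    testable without database downloads, plus a file-based command-line
    interface (edge lists, GMT gene sets, GraphML export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
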