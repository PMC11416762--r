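# Shared fixtures: tiny named graphs built in code, packaged file
# fixtures, and a random-graph generator for property-style tests.

net_from_edges <- function(a, b) {
  simplify_edges(data.frame(gene_a = a, gene_b = b,
                            stringsAsFactors = FALSE))
}

triangle_net <- function() net_from_edges(c("A", "B", "C"), c("B", "C", "A"))

path3_net <- function() net_from_edges(c("A", "B"), c("B", "C"))

star_net <- function(k = 3) {
  net_from_edges(rep("c", k), sprintf("l%d", seq_len(k)))
}

# Erdos-Renyi G(n, p) with deterministic vertex names, as a ppi_network.
random_net <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n))
  as_ppi_network(g)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "ppirank")
  if (!nzchar(path)) stop("missing packaged fixture: ", name)
  path
}

perm12_net <- function() read_edge_list(extdata("perm12_edges.tsv"))

# Compare two similarity matrices: same stored support, values within tol.
expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_equal(a$genes, b$genes)
  expect_equal(nrow(a$pairs), nrow(b$pairs))
  expect_equal(a$pairs$gene_a, b$pairs$gene_a)
  expect_equal(a$pairs$gene_b, b$pairs$gene_b)
  for (col in c("jaccard", "dice", "combined")) {
    expect_lt(max(abs(a$pairs[[col]] - b$pairs[[col]]), 0), tol)
  }
}
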