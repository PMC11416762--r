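test_that("pairwise scores reproduce the worked toy values", {
  # triangle: N(A)={B,C}, N(B)={A,C} -> J=1/3, SI=1/2, S=5/12
  expect_equal(jaccard_similarity(c("B", "C"), c("A", "C")), 1 / 3)
  expect_equal(dice_similarity(c("B", "C"), c("A", "C")), 1 / 2)
  expect_equal(combined_similarity(c("B", "C"), c("A", "C")), 5 / 12)
  # identical non-empty sets score 1 on all three
  expect_equal(jaccard_similarity("X", "X"), 1)
  expect_equal(dice_similarity(c("X", "Y"), c("Y", "X")), 1)
  # degenerate convention: both empty -> 0, not NaN
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
  expect_equal(dice_similarity(character(0), character(0)), 0)
  expect_equal(combined_similarity(character(0), character(0)), 0)
  # disjoint non-empty sets
  expect_equal(dice_similarity("A", "B"), 0)
})

test_that("neighbor_index returns open neighborhoods", {
  nb <- neighbor_index(triangle_net())
  expect_setequal(nb[["A"]], c("B", "C"))
  expect_setequal(nb[["B"]], c("A", "C"))
  star <- star_net(3)
  nbs <- neighbor_index(star)
  expect_setequal(nbs[["c"]], c("l1", "l2", "l3"))
  expect_equal(nbs[["l1"]], "c")
  lonely <- simplify_edges(data.frame(gene_a = "A", gene_b = "A"))
  expect_equal(neighbor_index(lonely)[["A"]], character(0))
})

test_that("build_similarity_matrix stores exactly the shared-neighbor pairs", {
  # path A-B-C: only (A,C) share a neighbor, with all scores 1
  sm <- build_similarity_matrix(path3_net())
  expect_equal(nrow(sm$pairs), 1L)
  expect_equal(sm$pairs$gene_a, "A")
  expect_equal(sm$pairs$gene_b, "C")
  expect_equal(unname(similarity_lookup(sm, "C", "A")), c(1, 1, 1))
  # lookup of an unstored pair is all-zero
  expect_equal(unname(similarity_lookup(sm, "A", "B")), c(0, 0, 0))

  # star K1,4: all 6 leaf pairs stored with combined 1; no center-leaf pair
  sm4 <- build_similarity_matrix(star_net(4))
  expect_equal(nrow(sm4$pairs), choose(4, 2))
  expect_true(all(sm4$pairs$combined == 1))
  expect_false("c" %in% c(sm4$pairs$gene_a, sm4$pairs$gene_b))

  # edgeless network: no stored pairs, but genes retained
  lonely <- simplify_edges(data.frame(gene_a = sprintf("v%d", 1:5),
                                      gene_b = sprintf("v%d", 1:5)))
  sme <- build_similarity_matrix(lonely)
  expect_equal(nrow(sme$pairs), 0L)
  expect_length(sme$genes, 5L)

  expect_error(build_similarity_matrix(simplify_edges(
    data.frame(gene_a = character(0), gene_b = character(0)))), "empty")
})

test_that("triangle matrix matches hand values and brute force disagrees nowhere", {
  sm <- build_similarity_matrix(triangle_net())
  expect_equal(nrow(sm$pairs), 3L)
  expect_true(all(abs(sm$pairs$jaccard - 1 / 3) < 1e-12))
  expect_true(all(abs(sm$pairs$dice - 1 / 2) < 1e-12))
  expect_true(all(abs(sm$pairs$combined - 5 / 12) < 1e-12))
  expect_same_matrix(sm, brute_force_matrix(triangle_net()))
})

test_that("sparse builder equals brute force on random graphs", {
  cases <- expand.grid(n = c(15, 40, 80), p = c(0.02, 0.1, 0.25))
  for (i in seq_len(nrow(cases))) {
    net <- random_net(cases$n[i], cases$p[i], seed = 100 + i)
    expect_same_matrix(build_similarity_matrix(net), brute_force_matrix(net))
  }
})

test_that("sparse builder agrees with igraph's own Jaccard", {
  net <- random_net(60, 0.12, seed = 7)
  sm <- build_similarity_matrix(net)
  ref <- igraph::similarity(net$graph, method = "jaccard", loops = FALSE)
  nm <- igraph::V(net$graph)$name
  dimnames(ref) <- list(nm, nm)
  for (r in seq_len(nrow(sm$pairs))) {
    expect_equal(sm$pairs$jaccard[r],
                 ref[sm$pairs$gene_a[r], sm$pairs$gene_b[r]],
                 tolerance = 1e-12)
  }
  # zero support agrees too: total nonzero off-diagonal entries match
  expect_equal(2L * nrow(sm$pairs), sum(ref > 0) - sum(diag(ref) > 0))
})

test_that("metric identities hold on random graphs", {
  for (s in 1:5) {
    net <- random_net(50, 0.1, seed = s)
    p <- build_similarity_matrix(net)$pairs
    expect_true(all(p$jaccard >= 0 & p$jaccard <= p$dice & p$dice <= 1))
    expect_true(all(abs(p$dice - 2 * p$jaccard / (1 + p$jaccard)) < 1e-12))
    expect_identical(p$combined, (p$jaccard + p$dice) / 2)
  }
})

test_that("stored support is exactly distance-<=2 pairs sharing a neighbor", {
  net <- random_net(40, 0.08, seed = 11)
  sm <- build_similarity_matrix(net)
  d <- igraph::distances(net$graph)
  nm <- igraph::V(net$graph)$name
  nb <- neighbor_index(net)
  stored <- paste(sm$pairs$gene_a, sm$pairs$gene_b)
  expected <- character(0)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j && d[i, j] <= 2 &&
        length(intersect(nb[[nm[i]]], nb[[nm[j]]])) >= 1) {
      expected <- c(expected, paste(min(nm[i], nm[j]), max(nm[i], nm[j])))
    }
  }
  expect_setequal(stored, expected)
})

test_that("closed neighborhoods make adjacency itself count", {
  # triangle under closed neighborhoods: N[A]=N[B]=N[C]={A,B,C} -> all 1
  smc <- build_similarity_matrix(triangle_net(), neighborhood = "closed")
  expect_true(all(smc$pairs$combined == 1))
  expect_same_matrix(smc,
                     brute_force_matrix(triangle_net(), neighborhood = "closed"))
  net <- random_net(30, 0.15, seed = 3)
  expect_same_matrix(build_similarity_matrix(net, neighborhood = "closed"),
                     brute_force_matrix(net, neighborhood = "closed"))
})

test_that("brute_force_matrix enforces its vertex cap", {
  net <- random_net(20, 0.2, seed = 1)
  expect_error(brute_force_matrix(net, max_vertices = 10), "cap")
})

test_that("matrix TSV persistence round-trips with sorted rows", {
  net <- random_net(30, 0.15, seed = 9)
  sm <- build_similarity_matrix(net)
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile()
  write_similarity(sm, f, genes_path = g)
  header <- readLines(f, n = 1)
  expect_equal(header, "gene_a\tgene_b\tjaccard\tdice\tcombined")
  back <- read_similarity(f, genes_path = g)
  expect_equal(back$genes, sm$genes)
  # fwrite serializes doubles at 15 significant digits, so the reload
  # agrees to ~1 ulp of that precision, not bit-for-bit
  expect_equal(as.data.frame(back$pairs), as.data.frame(sm$pairs),
               tolerance = 1e-12)
  # rows sorted lexicographically with gene_a < gene_b
  expect_true(all(sm$pairs$gene_a < sm$pairs$gene_b))
  expect_false(is.unsorted(sm$pairs$gene_a))
})
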