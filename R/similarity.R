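# Neighborhood-overlap similarity between gene pairs on a simple
# undirected PPI network:
#   J(A,B)  = |N(A) n N(B)| / |N(A) u N(B)|          (Jaccard)
#   SI(A,B) = 2|N(A) n N(B)| / (|N(A)| + |N(B)|)     (Sorensen-Dice)
#   S(A,B)  = (J + SI) / 2                           (integrated)
# Open neighborhoods by default (g not in N(g)); pairs whose neighborhood
# union is empty score 0 by convention so the matrix stays total-ordered.

#' Open neighborhoods of every vertex
#'
#' @param network A `ppi_network`.
#' @return Named list mapping each gene to the character vector of its
#'   neighbors (excluding itself); isolated vertices map to `character(0)`.
#' @export
neighbor_index <- function(network) {
  g <- network$graph
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  out <- lapply(adj, function(vs) igraph::V(g)$name[as.integer(vs)])
  names(out) <- igraph::V(g)$name
  out
}

#' Pairwise neighborhood similarity scores
#'
#' Set-based similarity between two neighbor sets. All three return 0 when
#' the relevant denominator is empty (two isolated vertices), a documented
#' convention that keeps scores finite and rankable.
#'
#' @param na,nb Character vectors: the (open) neighbor sets of two genes.
#' @return A score in `[0, 1]`.
#' @export
jaccard_similarity <- function(na, nb) {
  na <- unique(na)
  nb <- unique(nb)
  u <- length(union(na, nb))
  if (u == 0L) return(0)
  length(intersect(na, nb)) / u
}

#' @rdname jaccard_similarity
#' @export
dice_similarity <- function(na, nb) {
  na <- unique(na)
  nb <- unique(nb)
  denom <- length(na) + length(nb)
  if (denom == 0L) return(0)
  2 * length(intersect(na, nb)) / denom
}

#' @rdname jaccard_similarity
#' @export
combined_similarity <- function(na, nb) {
  (jaccard_similarity(na, nb) + dice_similarity(na, nb)) / 2
}

new_similarity_matrix <- function(genes, pairs, neighborhood, provenance = list()) {
  data.table::setkeyv(pairs, c("gene_a", "gene_b"))
  structure(list(genes = genes, pairs = pairs, neighborhood = neighborhood,
                 provenance = provenance),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d genes, %d stored pairs (%s neighborhoods)\n",
              length(x$genes), nrow(x$pairs), x$neighborhood))
  invisible(x)
}

#' Build the sparse gene-gene similarity matrix
#'
#' Stores one row per unordered gene pair sharing at least one neighbor
#' (equivalently, pairs at graph distance <= 2 with a common neighbor);
#' every unstored pair scores exactly 0. Common-neighbor counts come from
#' the square of the sparse adjacency matrix, so cost scales with the
#' number of distance-2 pairs rather than with all pairs.
#'
#' @param network A `ppi_network`.
#' @param neighborhood `"open"` (default; a vertex is not its own
#'   neighbor) or `"closed"` (adds the vertex itself, so adjacency alone
#'   contributes overlap).
#' @return A `similarity_matrix`: gene universe (sorted), a keyed
#'   data.table of pairs (`gene_a < gene_b`) with columns `jaccard`,
#'   `dice`, `combined`, and provenance.
#' @export
build_similarity_matrix <- function(network, neighborhood = c("open", "closed")) {
  neighborhood <- match.arg(neighborhood)
  nv <- n_vertices(network)
  if (nv == 0L) stop("cannot build a similarity matrix from an empty network")
  genes <- igraph::V(network$graph)$name
  A <- igraph::as_adjacency_matrix(network$graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  if (neighborhood == "open") {
    inter <- Matrix::crossprod(A)        # common-neighbor counts
    size <- deg
  } else {
    inter <- Matrix::crossprod(A) + 2 * A  # plus the endpoints themselves
    size <- deg + 1
  }
  ut <- methods::as(Matrix::triu(inter, k = 1L), "TsparseMatrix")
  keep <- ut@x > 0
  i <- ut@i[keep] + 1L
  j <- ut@j[keep] + 1L
  cn <- ut@x[keep]
  tot <- size[i] + size[j]
  pairs <- data.table::data.table(
    gene_a = pmin(genes[i], genes[j]),
    gene_b = pmax(genes[i], genes[j]),
    jaccard = cn / (tot - cn),
    dice = 2 * cn / tot
  )
  pairs[, combined := (jaccard + dice) / 2]
  data.table::setorder(pairs, gene_a, gene_b)
  new_similarity_matrix(sort(genes), pairs, neighborhood,
                        provenance = c(network$provenance,
                                       list(n_vertices = nv,
                                            n_edges = n_edges(network))))
}

#' All-pairs similarity by direct evaluation (test oracle)
#'
#' Evaluates the Jaccard/Dice/integrated formulas for every one of the
#' `choose(n, 2)` gene pairs straight from the neighbor sets, without the
#' sparse common-neighbor shortcut. Quadratic; capped by `max_vertices`.
#'
#' @inheritParams build_similarity_matrix
#' @param max_vertices Refuse networks larger than this (default 500).
#' @return A `similarity_matrix` holding only pairs with nonzero combined
#'   score, matching the sparse builder's storage convention.
#' @export
brute_force_matrix <- function(network, neighborhood = c("open", "closed"),
                               max_vertices = 500L) {
  neighborhood <- match.arg(neighborhood)
  nv <- n_vertices(network)
  if (nv == 0L) stop("cannot build a similarity matrix from an empty network")
  if (nv > max_vertices) {
    stop("brute_force_matrix: ", nv, " vertices exceeds cap of ", max_vertices)
  }
  nb <- neighbor_index(network)
  if (neighborhood == "closed") {
    nb <- stats::setNames(lapply(names(nb), function(v) union(v, nb[[v]])),
                          names(nb))
  }
  genes <- sort(names(nb))
  rows <- list()
  if (length(genes) >= 2L) {
    pr <- utils::combn(genes, 2L)
    ja <- numeric(ncol(pr))
    di <- numeric(ncol(pr))
    for (c0 in seq_len(ncol(pr))) {
      ja[c0] <- jaccard_similarity(nb[[pr[1, c0]]], nb[[pr[2, c0]]])
      di[c0] <- dice_similarity(nb[[pr[1, c0]]], nb[[pr[2, c0]]])
    }
    keep <- ja > 0 | di > 0
    rows <- data.table::data.table(
      gene_a = pr[1, keep], gene_b = pr[2, keep],
      jaccard = ja[keep], dice = di[keep]
    )
    rows[, combined := (jaccard + dice) / 2]
  } else {
    rows <- data.table::data.table(gene_a = character(0), gene_b = character(0),
                                   jaccard = numeric(0), dice = numeric(0),
                                   combined = numeric(0))
  }
  data.table::setorder(rows, gene_a, gene_b)
  new_similarity_matrix(genes, rows, neighborhood,
                        provenance = list(method = "brute_force"))
}

#' Look up the similarity scores of one gene pair
#'
#' @param matrix A `similarity_matrix`.
#' @param a,b Gene symbols (order irrelevant).
#' @return Named numeric vector `c(jaccard, dice, combined)`; all zero for
#'   pairs that are not stored (including identical genes).
#' @export
similarity_lookup <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (!a %in% matrix$genes) stop("gene not in matrix: ", a)
  if (!b %in% matrix$genes) stop("gene not in matrix: ", b)
  ga <- min(a, b)
  gb <- max(a, b)
  row <- matrix$pairs[.(ga, gb), nomatch = NULL]
  if (nrow(row) == 0L) {
    return(c(jaccard = 0, dice = 0, combined = 0))
  }
  c(jaccard = row$jaccard, dice = row$dice, combined = row$combined)
}

#' Similarity of one gene to every gene in the matrix
#'
#' @param matrix A `similarity_matrix`.
#' @param gene Gene symbol present in the matrix.
#' @param metric One of `"combined"`, `"jaccard"`, `"dice"`.
#' @return Named numeric vector over all matrix genes (self = 0, unstored
#'   pairs = 0).
#' @export
gene_similarity_vector <- function(matrix, gene,
                                   metric = c("combined", "jaccard", "dice")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (!gene %in% matrix$genes) stop("gene not in matrix: ", gene)
  v <- stats::setNames(numeric(length(matrix$genes)), matrix$genes)
  pa <- matrix$pairs[gene_a == gene]
  if (nrow(pa)) v[pa$gene_b] <- pa[[metric]]
  pb <- matrix$pairs[gene_b == gene]
  if (nrow(pb)) v[pb$gene_a] <- pb[[metric]]
  v
}

#' Persist and reload the sparse similarity matrix
#'
#' Triplet TSV with header `gene_a gene_b jaccard dice combined`, rows
#' sorted by (`gene_a`, `gene_b`) with `gene_a < gene_b`, so reruns are
#' byte-identical. The gene universe (including genes with no stored
#' pair) goes to a one-gene-per-line sidecar when `genes_path` is given;
#' without it, `read_similarity()` infers the universe from the pairs.
#'
#' @param matrix A `similarity_matrix`.
#' @param path TSV path for the pair triplets.
#' @param genes_path Optional path for the gene universe.
#' @return `write_similarity()` the path invisibly; `read_similarity()` a
#'   `similarity_matrix`.
#' @export
write_similarity <- function(matrix, path, genes_path = NULL) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  data.table::fwrite(matrix$pairs, path, sep = "\t")
  if (!is.null(genes_path)) writeLines(matrix$genes, genes_path)
  invisible(path)
}

#' @rdname write_similarity
#' @param neighborhood Neighborhood convention to record on the reloaded
#'   object (the TSV does not carry it).
#' @export
read_similarity <- function(path, genes_path = NULL, neighborhood = "open") {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  pairs <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("gene_a", "gene_b")))
  need <- c("gene_a", "gene_b", "jaccard", "dice", "combined")
  if (!all(need %in% names(pairs))) {
    stop("similarity file must have columns: ", paste(need, collapse = ", "))
  }
  genes <- if (!is.null(genes_path)) {
    sort(unique(readLines(genes_path, warn = FALSE)))
  } else {
    sort(unique(c(pairs$gene_a, pairs$gene_b)))
  }
  data.table::setorder(pairs, gene_a, gene_b)
  new_similarity_matrix(genes, pairs, neighborhood,
                        provenance = list(source = path))
}
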