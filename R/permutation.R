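# Permutation test of a query gene's association with a pathway: compare
# the gene's mean similarity to the pathway genes against the null
# distribution of its mean similarity to equally many genes drawn
# uniformly at random (without replacement) from the network. Empirical
# p uses the plus-one estimator p = (1 + #{null >= observed}) / (1 + B),
# so p is never zero and significance means "higher similarity than
# random gene sets".

#' Mean similarity of a gene to a gene set
#'
#' @param matrix A `similarity_matrix`.
#' @param gene Query gene symbol (must be in the matrix).
#' @param gene_set Character vector; restricted to matrix genes and the
#'   query gene itself is removed before averaging.
#' @param metric Similarity column to average.
#' @return Arithmetic mean over the effective set (its size is the
#'   denominator); error if the effective set is empty.
#' @export
mean_similarity_to_set <- function(matrix, gene, gene_set,
                                   metric = c("combined", "jaccard", "dice")) {
  metric <- match.arg(metric)
  if (!gene %in% matrix$genes) stop("gene not in matrix: ", gene)
  eff <- setdiff(intersect(unique(as.character(gene_set)), matrix$genes), gene)
  if (!length(eff)) stop("effective gene set is empty for gene ", gene)
  v <- gene_similarity_vector(matrix, gene, metric)
  mean(v[eff])
}

#' Permutation test of gene-pathway similarity
#'
#' Draws `n_perm` random gene sets of size `set_size` uniformly without
#' replacement from the sampling pool (all matrix genes minus the query;
#' optionally also minus the pathway), records the query's mean
#' similarity to each, and compares the observed pathway mean against
#' this null with the plus-one empirical p-value. Fully reproducible
#' given `rng_seed`.
#'
#' @inheritParams mean_similarity_to_set
#' @param pathway Character vector of pathway gene symbols.
#' @param n_perm Number of random sets (default 10000).
#' @param set_size Genes per random set (default 50), or `"match"` to use
#'   the pathway's effective size.
#' @param rng_seed Integer seed; recorded in the result.
#' @param exclude_pathway Also remove pathway genes from the sampling
#'   pool (default `FALSE`: the pool is the whole gene list minus the
#'   query).
#' @param pathway_name Label carried into the result.
#' @return A `permutation_result`: observed mean, the `n_perm` null
#'   means, `p_empirical`, sizes, and RNG provenance.
#' @export
permutation_test <- function(matrix, gene, pathway, n_perm = 10000L,
                             set_size = 50L, rng_seed = 1L,
                             exclude_pathway = FALSE,
                             metric = c("combined", "jaccard", "dice"),
                             pathway_name = NA_character_) {
  metric <- match.arg(metric)
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  eff_pathway <- setdiff(
    intersect(unique(as.character(pathway)), matrix$genes), gene)
  observed <- mean_similarity_to_set(matrix, gene, eff_pathway, metric)
  pool <- setdiff(matrix$genes, gene)
  if (isTRUE(exclude_pathway)) pool <- setdiff(pool, eff_pathway)
  if (identical(set_size, "match")) set_size <- length(eff_pathway)
  if (!is.numeric(set_size) || set_size < 1) stop("set_size must be >= 1")
  set_size <- as.integer(set_size)
  if (set_size > length(pool)) {
    stop("sampling pool too small: ", length(pool), " genes for set_size ",
         set_size)
  }
  v <- gene_similarity_vector(matrix, gene, metric)[pool]
  n_perm <- as.integer(n_perm)
  null_means <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_perm),
           function(i) mean(v[sample.int(length(v), set_size)]),
           numeric(1))
  })
  p <- (1 + sum(null_means >= observed)) / (1 + n_perm)
  structure(
    list(query_gene = gene, pathway_name = pathway_name,
         observed_mean = observed, null_means = null_means,
         p_empirical = p, n_perm = n_perm, set_size = set_size,
         n_pathway_used = length(eff_pathway), rng_seed = rng_seed,
         metric = metric),
    class = "permutation_result")
}

#' Exact permutation p-value by subset enumeration (test oracle)
#'
#' Enumerates every size-`set_size` subset of the sampling pool, computes
#' the query's mean similarity to each, and applies the same `>=`
#' comparison and plus-one convention to the full enumeration count:
#' p = (1 + #{subsets >= observed}) / (1 + C(pool, set_size)).
#'
#' @inheritParams permutation_test
#' @param max_subsets Refuse enumerations larger than this (default 1e6).
#' @return List with `p_exact`, `observed_mean`, `tail_fraction`
#'   (#\{subset mean >= observed\} / #subsets, the plus-one-free tail
#'   probability that Monte Carlo sampling estimates), `null_means`, and
#'   `n_subsets`.
#' @export
exact_permutation_p <- function(matrix, gene, pathway, set_size = 2L,
                                exclude_pathway = FALSE,
                                metric = c("combined", "jaccard", "dice"),
                                max_subsets = 1e6) {
  metric <- match.arg(metric)
  eff_pathway <- setdiff(
    intersect(unique(as.character(pathway)), matrix$genes), gene)
  observed <- mean_similarity_to_set(matrix, gene, eff_pathway, metric)
  pool <- setdiff(matrix$genes, gene)
  if (isTRUE(exclude_pathway)) pool <- setdiff(pool, eff_pathway)
  set_size <- as.integer(set_size)
  if (set_size < 1 || set_size > length(pool)) {
    stop("set_size must be in [1, pool size]")
  }
  n_subsets <- choose(length(pool), set_size)
  if (n_subsets > max_subsets) {
    stop("enumeration of ", n_subsets, " subsets exceeds cap of ", max_subsets)
  }
  v <- gene_similarity_vector(matrix, gene, metric)[pool]
  idx <- utils::combn(length(pool), set_size)
  null_means <- Matrix::colMeans(matrix(v[as.vector(idx)], nrow = set_size))
  n_ge <- sum(null_means >= observed)
  list(p_exact = (1 + n_ge) / (1 + n_subsets),
       observed_mean = observed,
       tail_fraction = n_ge / n_subsets,
       null_means = null_means,
       n_subsets = n_subsets)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: gene %s vs %s\n", x$query_gene,
              if (is.na(x$pathway_name)) "gene set" else x$pathway_name))
  cat(sprintf("  observed mean similarity: %.6g\n", x$observed_mean))
  cat(sprintf("  empirical p: %.4g  (n_perm = %d, set_size = %d, seed = %d)\n",
              x$p_empirical, x$n_perm, x$set_size, x$rng_seed))
  cat(text_histogram(x$null_means, x$observed_mean), sep = "\n")
  invisible(x)
}

# Crude fixed-width histogram of the null with a marker at the observed
# value; good enough for a terminal sanity check.
text_histogram <- function(values, observed = NULL, bins = 20L, width = 40L) {
  rng <- range(c(values, observed), finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(values, breaks, all.inside = TRUE), bins)
  bars <- strrep("#", pmax(0L, round(counts / max(counts, 1L) * width)))
  marker <- if (!is.null(observed)) {
    findInterval(observed, breaks, all.inside = TRUE)
  } else 0L
  sprintf("  %s%8.4f | %s", ifelse(seq_len(bins) == marker, ">", " "),
          breaks[-length(breaks)], bars)
}

#' Serialize a permutation result to JSON
#'
#' @param result A `permutation_result`.
#' @param path Output JSON path.
#' @param null_means_path Optional TSV of the null means.
#' @return `path`, invisibly.
#' @export
write_permutation_result <- function(result, path, null_means_path = NULL) {
  stopifnot(inherits(result, "permutation_result"))
  out <- result[c("query_gene", "pathway_name", "observed_mean",
                  "p_empirical", "n_perm", "set_size", "n_pathway_used",
                  "rng_seed", "metric")]
  out$null_mean_mean <- mean(result$null_means)
  out$null_mean_sd <- stats::sd(result$null_means)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(null_means_path)) {
    data.table::fwrite(data.table::data.table(null_mean = result$null_means),
                       null_means_path, sep = "\t")
  }
  invisible(path)
}
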