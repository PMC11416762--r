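# Seed-set ("osteo-specific") scoring: each gene's score is the sum of
# its integrated similarity to every seed gene present in the network,
# excluding the self term; genes are then ranked by descending score.

#' Summed similarity of one gene to a seed set
#'
#' @param matrix A `similarity_matrix`.
#' @param seed Character vector of seed gene symbols; silently restricted
#'   to the matrix gene universe. The gene's own seed membership never
#'   contributes (self term excluded).
#' @param gene Gene symbol; must be in the matrix.
#' @param metric Similarity to sum: `"combined"` (default), `"jaccard"`,
#'   or `"dice"`.
#' @return Non-negative numeric score.
#' @export
seed_score <- function(matrix, seed, gene,
                       metric = c("combined", "jaccard", "dice")) {
  metric <- match.arg(metric)
  if (!gene %in% matrix$genes) stop("gene not in matrix: ", gene)
  eff <- setdiff(intersect(unique(as.character(seed)), matrix$genes), gene)
  if (!length(eff)) return(0)
  v <- gene_similarity_vector(matrix, gene, metric)
  sum(v[eff])
}

#' Rank all network genes by seed-set similarity
#'
#' Produces one row per network gene: its summed similarity to the
#' effective seed (seed genes found in the matrix), a dense 1-based rank,
#' and a seed-membership flag. Ties are broken lexicographically by gene
#' symbol so the table is reproducible byte for byte. With
#' `exclude_seed = TRUE` (the usual reporting mode) seed genes are
#' dropped before ranking.
#'
#' @inheritParams seed_score
#' @param exclude_seed Drop seed genes from the ranked table.
#' @return A `score_table`: data.table with columns `rank`, `gene`,
#'   `score`, `is_seed`, plus attribute `n_seed_used`.
#' @export
rank_genes <- function(matrix, seed, exclude_seed = TRUE,
                       metric = c("combined", "jaccard", "dice")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "similarity_matrix"))
  eff_seed <- intersect(unique(as.character(seed)), matrix$genes)
  if (!length(eff_seed)) stop("no seed genes present in the network")
  sc <- stats::setNames(numeric(length(matrix$genes)), matrix$genes)
  p <- matrix$pairs
  pa <- p[gene_a %in% eff_seed, .(gene = gene_b, s = .SD[[1L]]),
          .SDcols = metric]
  pb <- p[gene_b %in% eff_seed, .(gene = gene_a, s = .SD[[1L]]),
          .SDcols = metric]
  contrib <- data.table::rbindlist(list(pa, pb))[, .(s = sum(s)), by = gene]
  if (nrow(contrib)) sc[contrib$gene] <- contrib$s
  tab <- data.table::data.table(
    gene = matrix$genes,
    score = unname(sc),
    is_seed = matrix$genes %in% eff_seed
  )
  if (isTRUE(exclude_seed)) tab <- tab[is_seed == FALSE]
  if (nrow(tab) == 0L) stop("no genes left to rank after excluding the seed")
  data.table::setorder(tab, -score, gene)
  tab[, rank := seq_len(.N)]
  data.table::setcolorder(tab, c("rank", "gene", "score", "is_seed"))
  data.table::setattr(tab, "n_seed_used", length(eff_seed))
  data.table::setattr(tab, "metric", metric)
  data.table::setattr(tab, "class", c("score_table", class(tab)))
  tab[]
}

#' First k rows of a score table
#'
#' @param table A `score_table` from [rank_genes()].
#' @param k Positive integer; `k` larger than the table returns the whole
#'   table.
#' @return A `score_table` with `min(k, nrow)` rows, order preserved.
#' @export
top_k <- function(table, k) {
  stopifnot(inherits(table, "score_table"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  out <- table[seq_len(min(as.integer(k), nrow(table)))]
  data.table::setattr(out, "n_seed_used", attr(table, "n_seed_used"))
  data.table::setattr(out, "metric", attr(table, "metric"))
  data.table::setattr(out, "class", class(table))
  out[]
}

#' Write a score table as TSV with a JSON metadata sidecar
#'
#' @param table A `score_table`.
#' @param path Output TSV (`rank gene score is_seed`).
#' @param meta_path Optional JSON sidecar path; records seed sizes,
#'   scoring options, and any extra fields in `extra`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, meta_path = NULL, extra = list()) {
  stopifnot(inherits(table, "score_table"))
  data.table::fwrite(table, path, sep = "\t")
  if (!is.null(meta_path)) {
    meta <- c(list(n_rows = nrow(table),
                   n_seed_used = attr(table, "n_seed_used"),
                   metric = attr(table, "metric"),
                   self_similarity_excluded = TRUE),
              extra)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
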