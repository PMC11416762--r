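# Minimal over-representation analysis (ORA): hypergeometric upper-tail
# test of a query gene list against annotation gene sets inside a fixed
# gene universe, with Benjamini-Hochberg adjustment across the emitted
# terms and a significance call at p_adjusted < alpha.

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' are annotated. Computed via `stats::phyper` on the complement, which
#' is numerically stable for the small counts ORA deals in.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return p in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != floor(vals))) {
    stop("k, K, n, N must be integers")
  }
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    stop("require 0 <= k <= min(K, n), K <= N, n <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort ascending, multiply the i-th smallest by
#' m/i, enforce monotone non-decrease from the largest rank down, cap at
#' 1; results are returned in the original input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order; elementwise >= the
#'   input and <= 1.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p_values[o] * m / (m:1)))[ro]
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric test per annotation set with overlap at least
#' `min_overlap`; BH adjustment is applied across exactly the emitted
#' rows (one collection at a time, as per-ontology enrichment tools do).
#' Query genes outside the universe are dropped with a warning; term
#' membership is likewise counted within the universe only.
#'
#' @param query Character vector of candidate genes (e.g. a top-k slice
#'   of a score table).
#' @param annotations A `gene_set_collection` of annotation terms.
#' @param universe Character vector defining the background (typically
#'   the network vertex set).
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @param min_overlap Minimum overlap k for a term to be reported
#'   (default 1; disjoint terms are omitted).
#' @return data.table with columns `term, k, K, n, N, p_raw, p_adjusted,
#'   significant`, sorted by `p_raw` then term name.
#' @export
ora <- function(query, annotations, universe, alpha = 0.01, min_overlap = 1L) {
  stopifnot(inherits(annotations, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("no query genes left after restricting to universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations$sets), function(nm) {
    term_genes <- intersect(annotations$sets[[nm]], universe)
    k <- length(intersect(query, term_genes))
    if (k < min_overlap || !length(term_genes)) return(NULL)
    data.table::data.table(term = nm, k = k, K = length(term_genes),
                           n = n, N = N,
                           p_raw = hypergeom_tail(k, length(term_genes), n, N))
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    return(data.table::data.table(term = character(0), k = integer(0),
                                  K = integer(0), n = integer(0),
                                  N = integer(0), p_raw = numeric(0),
                                  p_adjusted = numeric(0),
                                  significant = logical(0)))
  }
  out[, p_adjusted := bh_adjust(p_raw)]
  out[, significant := p_adjusted < alpha]
  data.table::setorder(out, p_raw, term)
  out[]
}

#' Write an enrichment table as TSV
#'
#' @param table Result of [ora()].
#' @param path Output path (`term k K n N p_raw p_adjusted significant`).
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}
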