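# Planted-partition synthetic networks: a sparse background plus one or
# more cohesive modules whose members share many neighbors, emulating
# the pathway cohesion that guilt-by-association scoring relies on.
# Each module is split into "seed" genes (the known pathway) and
# held-out genes used to measure ranking recovery.

#' Specify a planted-module synthetic network
#'
#' Every intra-module vertex pair receives an edge independently with
#' probability `p_in`, every other pair (background-background,
#' background-module, cross-module) with `p_out`. Vertex names are
#' deterministic: background `G000001...`, module members `M1_001...`,
#' so tie-breaking and diffs are stable across runs.
#'
#' @param n_background Number of background vertices.
#' @param module_sizes Integer vector, one entry per planted module.
#' @param p_in Intra-module edge probability; must satisfy
#'   `0 <= p_out <= p_in <= 1` (equality gives the null model with no
#'   planted signal).
#' @param p_out Background / cross edge probability.
#' @param n_heldout_per_module How many genes of each module are withheld
#'   from the seed list (recycled; each entry < its module size).
#' @param rng_seed Integer seed controlling edge sampling.
#' @return A `synthetic_network_spec` list.
#' @export
synthetic_network_spec <- function(n_background = 500L, module_sizes = 30L,
                                   p_in = 0.3, p_out = 0.02,
                                   n_heldout_per_module = 10L,
                                   rng_seed = 1L) {
  n_background <- as.integer(n_background)
  module_sizes <- as.integer(module_sizes)
  n_heldout_per_module <- as.integer(rep(n_heldout_per_module,
                                         length.out = length(module_sizes)))
  if (n_background < 0L || any(module_sizes < 1L)) {
    stop("n_background must be >= 0 and module sizes >= 1")
  }
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("require 0 <= p_out <= p_in <= 1")
  }
  if (any(n_heldout_per_module < 0L) ||
      any(n_heldout_per_module >= module_sizes)) {
    stop("n_heldout_per_module must satisfy 0 <= h < module size")
  }
  structure(list(n_background = n_background, module_sizes = module_sizes,
                 p_in = p_in, p_out = p_out,
                 n_heldout_per_module = n_heldout_per_module,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_network_spec")
}

synthetic_vertex_names <- function(spec) {
  mods <- lapply(seq_along(spec$module_sizes), function(m) {
    sprintf("M%d_%03d", m, seq_len(spec$module_sizes[[m]]))
  })
  list(modules = mods,
       background = if (spec$n_background > 0L) {
         sprintf("G%06d", seq_len(spec$n_background))
       } else character(0))
}

#' Generate a planted-module network and its ground truth
#'
#' Independent Bernoulli draws over all vertex pairs (O(n^2) memory in
#' the total vertex count; intended for networks up to a few thousand
#' vertices). The result is already simple: no self-loops or duplicate
#' edges can arise, and vertices left isolated by sampling are retained.
#'
#' @param spec A `synthetic_network_spec`.
#' @return List with `network` (a `ppi_network`) and `truth` (a
#'   `synthetic_truth`: per module the seed and held-out gene names, the
#'   background genes, and the spec echo).
#' @export
generate_planted_module_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  nm <- synthetic_vertex_names(spec)
  vertices <- c(unlist(nm$modules), nm$background)
  module_id <- c(rep(seq_along(nm$modules), lengths(nm$modules)),
                 rep(0L, length(nm$background)))
  n <- length(vertices)
  if (n < 1L) stop("spec generates no vertices")
  edges <- if (n >= 2L) {
    pr <- utils::combn(n, 2L)
    same <- module_id[pr[1, ]] == module_id[pr[2, ]] & module_id[pr[1, ]] > 0L
    prob <- ifelse(same, spec$p_in, spec$p_out)
    keep <- withr::with_seed(spec$rng_seed,
                             stats::runif(ncol(pr)) < prob)
    data.frame(gene_a = vertices[pr[1, keep]],
               gene_b = vertices[pr[2, keep]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE))
  network <- new_ppi_network(
    g, provenance = list(source = "synthetic planted-partition",
                         spec = unclass(spec)))
  modules <- lapply(seq_along(nm$modules), function(m) {
    genes <- nm$modules[[m]]
    h <- spec$n_heldout_per_module[[m]]
    list(name = sprintf("M%d", m),
         seed = genes[seq_len(length(genes) - h)],
         heldout = if (h > 0L) genes[(length(genes) - h + 1L):length(genes)]
                   else character(0))
  })
  truth <- structure(list(modules = modules, background = nm$background,
                          spec = spec),
                     class = "synthetic_truth")
  list(network = network, truth = truth)
}

#' Persist the synthetic ground truth
#'
#' Writes a GMT with two sets per module (`M1_seed`, `M1_heldout`) and a
#' two-column TSV labelling every vertex as `background`, `<module>_seed`
#' or `<module>_heldout`.
#'
#' @param truth A `synthetic_truth`.
#' @param gmt_path Output GMT path.
#' @param tsv_path Output labels TSV path.
#' @return Invisible list of the two paths.
#' @export
write_truth <- function(truth, gmt_path, tsv_path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sets <- list()
  descriptions <- character(0)
  labels <- data.table::data.table(gene = character(0), label = character(0))
  for (mod in truth$modules) {
    sets[[paste0(mod$name, "_seed")]] <- mod$seed
    descriptions[[paste0(mod$name, "_seed")]] <- "planted module seed genes"
    labels <- data.table::rbindlist(list(
      labels, data.table::data.table(gene = mod$seed,
                                     label = paste0(mod$name, "_seed"))))
    if (length(mod$heldout)) {
      sets[[paste0(mod$name, "_heldout")]] <- mod$heldout
      descriptions[[paste0(mod$name, "_heldout")]] <-
        "planted module held-out genes"
      labels <- data.table::rbindlist(list(
        labels, data.table::data.table(gene = mod$heldout,
                                       label = paste0(mod$name, "_heldout"))))
    }
  }
  labels <- data.table::rbindlist(list(
    labels, data.table::data.table(gene = truth$background,
                                   label = "background")))
  write_gmt(gene_set_collection(sets, descriptions), gmt_path)
  data.table::fwrite(labels, tsv_path, sep = "\t")
  invisible(list(gmt = gmt_path, tsv = tsv_path))
}

#' Held-out gene recovery experiment
#'
#' For each replicate: generate a network from `spec` (advancing the seed
#' by one per replicate), build the similarity matrix, rank non-seed
#' genes against the union of all module seed sets, and record the
#' fraction of held-out module genes landing in the top
#' `ceiling(top_fraction * n_nonseed)` rows. With `p_in = p_out` the
#' held-out genes are exchangeable with the background and the expected
#' fraction is about `top_fraction` (null calibration).
#'
#' @param spec A `synthetic_network_spec`.
#' @param n_reps Number of replicates (>= 1).
#' @param top_fraction Fraction of the non-seed ranking counted as "top".
#' @return List with per-replicate `fractions`, their `mean` and `sd`,
#'   and the experiment settings.
#' @export
recovery_experiment <- function(spec, n_reps = 25L, top_fraction = 0.05) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  if (!is.numeric(n_reps) || n_reps < 1) stop("n_reps must be >= 1")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  fractions <- vapply(seq_len(as.integer(n_reps)), function(r) {
    sp <- spec
    sp$rng_seed <- spec$rng_seed + r - 1L
    sim <- generate_planted_module_network(sp)
    sm <- build_similarity_matrix(sim$network)
    seed <- unlist(lapply(sim$truth$modules, `[[`, "seed"))
    heldout <- unlist(lapply(sim$truth$modules, `[[`, "heldout"))
    if (!length(heldout)) stop("spec holds out no genes")
    tab <- rank_genes(sm, seed, exclude_seed = TRUE)
    n_top <- min(nrow(tab), max(1L, ceiling(top_fraction * nrow(tab))))
    mean(heldout %in% tab$gene[seq_len(n_top)])
  }, numeric(1))
  list(fractions = fractions, mean = mean(fractions), sd = stats::sd(fractions),
       n_reps = as.integer(n_reps), top_fraction = top_fraction, spec = spec)
}
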