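# Network container and file I/O: edge lists (generic and STRING
# protein.links dialects), GMT gene sets, GraphML export.

new_ppi_network <- function(graph, provenance = list()) {
  structure(list(graph = graph, provenance = provenance),
            class = "ppi_network")
}

#' Wrap an igraph graph as a simple undirected PPI network
#'
#' The graph is coerced to undirected and simplified (multi-edges and
#' self-loops removed); vertices must carry a `name` attribute holding the
#' gene symbol. Isolated vertices are retained.
#'
#' @param graph An igraph object with named vertices.
#' @param provenance Free-form list recording where the graph came from.
#' @return A `ppi_network` object.
#' @export
as_ppi_network <- function(graph, provenance = list()) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  new_ppi_network(graph, provenance)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d vertices, %d edges\n",
              n_vertices(x), n_edges(x)))
  if (length(x$provenance$source)) {
    cat("  source:", x$provenance$source, "\n")
  }
  invisible(x)
}

#' Vertex and edge accessors for a PPI network
#'
#' @param network A `ppi_network`.
#' @return `network_vertices()` a character vector of gene symbols;
#'   `network_edges()` a two-column character matrix with each unordered
#'   edge stored once, endpoints sorted within a row; `n_vertices()` /
#'   `n_edges()` counts.
#' @export
network_vertices <- function(network) {
  igraph::V(network$graph)$name
}

#' @rdname network_vertices
#' @export
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph, names = TRUE)
  if (nrow(e) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  out <- cbind(gene_a = pmin(e[, 1], e[, 2]), gene_b = pmax(e[, 1], e[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @rdname network_vertices
#' @export
n_vertices <- function(network) igraph::vcount(network$graph)

#' @rdname network_vertices
#' @export
n_edges <- function(network) igraph::ecount(network$graph)

#' Simplify a raw edge list into a PPI network
#'
#' Removes self-loops and duplicate edges (including reversed duplicates:
#' (a,b) and (b,a) collapse to one undirected edge). Endpoints that only
#' appeared in self-loops are retained as isolated vertices so vertex
#' counts are stable.
#'
#' @param edges A data.frame with character columns `gene_a`, `gene_b`.
#' @param provenance Optional provenance list stored on the result.
#' @return A `ppi_network`.
#' @export
simplify_edges <- function(edges, provenance = list()) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    a <- as.character(edges[[1]])
    b <- as.character(edges[[2]])
    if (any(!nzchar(a)) || any(!nzchar(b))) {
      stop("edge endpoints must be non-empty gene symbols")
    }
  } else {
    a <- b <- character(0)
  }
  vertices <- unique(c(a, b))
  keep <- a != b
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  provenance$n_raw_edges <- length(a)
  provenance$n_edges <- igraph::ecount(g)
  new_ppi_network(g, provenance)
}

#' Read an interaction network from an edge-list file
#'
#' Two dialects are supported: `"generic"` (two whitespace- or
#' tab-separated gene-symbol columns with an optional third numeric weight
#' column) and `"string-links"` (the STRING protein.links format with
#' header line `protein1 protein2 combined_score`, confidence scores
#' 0-1000). Lines starting with `#` and blank lines are skipped. The
#' parsed edges are simplified (self-loops and duplicate edges removed).
#'
#' @param path Path to the edge-list file.
#' @param dialect `"generic"` or `"string-links"`.
#' @param min_weight Optional threshold: edges with weight strictly below
#'   it are dropped before simplification. Unweighted rows are kept.
#' @param mapping Optional path to a two-column TSV (`source_id TAB
#'   symbol`) applied to both endpoints before simplification; ids absent
#'   from the mapping are kept verbatim. When two ids collapse to one
#'   symbol their neighborhoods are merged by the re-simplification.
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path, dialect = c("generic", "string-links"),
                           min_weight = NULL, mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (dialect == "string-links") {
    if (!length(lines)) stop("empty STRING links file: ", path)
    header <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
    if (!identical(header, c("protein1", "protein2", "combined_score"))) {
      stop("line ", lineno[[1]],
           ": expected STRING header 'protein1 protein2 combined_score'")
    }
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  want <- if (dialect == "string-links") 3L else c(2L, 3L)
  bad <- which(!nf %in% want)
  if (length(bad)) {
    stop("line ", lineno[bad[[1]]], ": expected ",
         paste(want, collapse = "-"), " columns, got ", nf[bad[[1]]])
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  w <- rep(NA_real_, length(toks))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(toks[has_w], `[[`, character(1), 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum)) {
      bad <- lineno[has_w][which(is.na(wnum))[[1]]]
      stop("line ", bad, ": non-numeric weight")
    }
    w[has_w] <- wnum
  }
  if (any(w < 0, na.rm = TRUE)) {
    stop("line ", lineno[which(w < 0)[[1]]], ": negative weight")
  }
  if (!is.null(min_weight)) {
    drop <- !is.na(w) & w < min_weight
    a <- a[!drop]
    b <- b[!drop]
    w <- w[!drop]
  }
  if (!is.null(mapping)) {
    map <- read_id_mapping(mapping)
    a <- ifelse(a %in% names(map), unname(map[a]), a)
    b <- ifelse(b %in% names(map), unname(map[b]), b)
  }
  net <- simplify_edges(
    data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE),
    provenance = list(source = path, dialect = dialect,
                      min_weight = min_weight, mapping = mapping)
  )
  if (n_vertices(net) == 0L) stop("empty network after parsing: ", path)
  net
}

read_id_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  toks <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) stop("mapping line ", bad[[1]], ": expected 2 columns")
  stats::setNames(vapply(toks, `[[`, character(1), 2L),
                  vapply(toks, `[[`, character(1), 1L))
}

# ---- gene set collections (GMT) ------------------------------------------

new_gene_set_collection <- function(sets, descriptions) {
  stopifnot(is.list(sets), length(sets) == length(descriptions))
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' Build a gene set collection in memory
#'
#' @param sets Named list of character vectors (duplicate genes within a
#'   set are dropped, first occurrence kept).
#' @param descriptions Optional character vector of descriptions, recycled
#'   from `""`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- stats::setNames(as.character(descriptions), names(sets))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  new_gene_set_collection(sets, descriptions)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d unique genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' Extract one gene set by name
#'
#' @param collection A `gene_set_collection`.
#' @param name Set name; unknown names are an error listing the available
#'   sets.
#' @return Character vector of gene symbols.
#' @export
get_gene_set <- function(collection, name) {
  if (!name %in% names(collection$sets)) {
    stop("unknown gene set '", name, "'; available: ",
         paste(names(collection$sets), collapse = ", "))
  }
  collection$sets[[name]]
}

#' Read and write gene sets in GMT format
#'
#' GMT holds one set per line: `name TAB description TAB gene TAB gene...`.
#' Duplicate genes within a set keep their first occurrence; trailing
#' empty fields are ignored. `write_gmt()` followed by `read_gmt()`
#' reproduces the collection exactly.
#'
#' @param path File path.
#' @param collection A `gene_set_collection`.
#' @return `read_gmt()` a `gene_set_collection`; `write_gmt()` the path,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  sets <- list()
  descriptions <- character(0)
  for (i in nonblank) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": expected at least 3 tab-separated fields")
    }
    nm <- fields[[1]]
    genes <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (!length(genes)) stop("GMT line ", i, ": set '", nm, "' has no genes")
    if (nm %in% names(sets)) stop("GMT line ", i, ": duplicate set '", nm, "'")
    sets[[nm]] <- genes
    descriptions[[nm]] <- fields[[2]]
  }
  new_gene_set_collection(sets, descriptions)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split a gene list by network membership
#'
#' @param genes Character vector of gene symbols.
#' @param network A `ppi_network`.
#' @return List with `present` (genes found among the network vertices,
#'   input order preserved) and `absent` (the rest).
#' @export
restrict_to_network <- function(genes, network) {
  genes <- as.character(genes)
  v <- network_vertices(network)
  hit <- genes %in% v
  out <- list(present = genes[hit], absent = genes[!hit])
  message(sprintf("restrict_to_network: %d/%d genes present in network",
                  length(out$present), length(genes)))
  out
}

#' Export a network as GraphML
#'
#' Writes standard undirected GraphML with the gene symbol as the node id.
#'
#' @param network A `ppi_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  for (v in network_vertices(network)) {
    xml2::xml_add_child(graph, "node", id = v)
  }
  e <- network_edges(network)
  for (i in seq_len(nrow(e))) {
    xml2::xml_add_child(graph, "edge", source = e[i, 1], target = e[i, 2])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
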