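#' Protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over gene-symbol nodes,
#' backed by an [igraph][igraph::igraph-package] graph. Edges may carry a
#' confidence score in \[0, 1\] and nodes may carry tags (e.g. `"EMT"`,
#' `"Rab"`). Self-loops and duplicate (unordered) edges are dropped at
#' construction; for duplicates the first confidence encountered is kept.
#' All downstream computation treats the graph as unweighted ("binary");
#' confidences are retained only for ranking and reporting.
#'
#' Node identity is the exact, case-sensitive gene-symbol string; symbol
#' harmonization across sources is the caller's responsibility.
#'
#' @param edges data frame with character columns `node_a`, `node_b` and an
#'   optional numeric `score` (or `confidence`) column; `NULL` for an
#'   edgeless network.
#' @param nodes additional isolated node symbols to include.
#' @return An object of class `ppi_network`.
#' @examples
#' net <- ppi_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C")))
#' network_nodes(net)
#' @export
ppi_network <- function(edges = NULL, nodes = character(0)) {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(nodes) > 0) g <- igraph::add_vertices(g, length(nodes), name = unique(nodes))
  } else {
    a <- as.character(edges$node_a)
    b <- as.character(edges$node_b)
    conf <- edges$score %||% edges$confidence %||% rep(1, length(a))
    conf <- as.numeric(conf)
    keep <- a != b
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    dup <- duplicated(edge_key(lo, hi))
    df <- data.frame(from = lo[!dup], to = hi[!dup], confidence = conf[!dup],
                     stringsAsFactors = FALSE)
    verts <- unique(c(nodes, df$from, df$to, a, b))
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = verts))
  }
  if (igraph::vcount(g) > 0) igraph::V(g)$tags <- ""
  structure(list(graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
  tags <- unique(unlist(strsplit(igraph::V(g)$tags %||% character(0), ";", fixed = TRUE)))
  tags <- setdiff(tags, "")
  if (length(tags) > 0) cat("  tags:", paste(tags, collapse = ", "), "\n")
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the node symbols, `network_edges()` the canonical
#' undirected edge table (columns `node_a`, `node_b`, `confidence`, sorted for
#' reproducible output) and `as_igraph()` the underlying igraph object.
#'
#' @param net a [ppi_network()].
#' @return Character vector, data frame, or igraph object respectively.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  as.character(igraph::V(net$graph)$name %||% character(0))
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(node_a = character(0), node_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  df <- igraph::as_data_frame(g, what = "edges")
  conf <- df$confidence %||% rep(1, nrow(df))
  out <- data.frame(node_a = pmin(df$from, df$to), node_b = pmax(df$from, df$to),
                    confidence = conf, stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname network_nodes
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$graph
}

#' Tag nodes and query tags
#'
#' Tags are free-text labels attached to nodes (`"EMT"`, `"hub"`, ...).
#' `tag_nodes()` adds a tag to the given nodes; symbols absent from the
#' network are ignored. `nodes_with_tag()` lists nodes carrying a tag.
#'
#' @param net a [ppi_network()].
#' @param nodes node symbols to tag.
#' @param tag single tag string.
#' @return `tag_nodes()` the modified network; `nodes_with_tag()` a character
#'   vector of symbols.
#' @export
tag_nodes <- function(net, nodes, tag) {
  stopifnot(inherits(net, "ppi_network"), is.character(tag), length(tag) == 1)
  g <- net$graph
  idx <- match(nodes, igraph::V(g)$name)
  idx <- idx[!is.na(idx)]
  if (length(idx) > 0) {
    cur <- igraph::V(g)$tags[idx]
    has <- vapply(strsplit(cur, ";", fixed = TRUE), function(t) tag %in% t, logical(1))
    upd <- ifelse(has, cur, ifelse(cur == "", tag, paste(cur, tag, sep = ";")))
    igraph::V(g)$tags[idx] <- upd
  }
  net$graph <- g
  net
}

#' @rdname tag_nodes
#' @export
nodes_with_tag <- function(net, tag) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) return(character(0))
  has <- vapply(strsplit(igraph::V(g)$tags, ";", fixed = TRUE),
                function(t) tag %in% t, logical(1))
  as.character(igraph::V(g)$name[has])
}
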