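#' Read an interaction edge table
#'
#' Ingests an undirected edge list from disk. Two dialects are supported:
#' \describe{
#'   \item{`generic`}{tab-separated with a header row and columns `node_a`,
#'     `node_b` and optionally `score` in \[0, 1\]; a missing score column
#'     defaults every row to 1.}
#'   \item{`string_links`}{the STRING protein-links export: whitespace
#'     separated with columns `protein1`, `protein2`, `combined_score`, the
#'     score an integer in 0--1000 which is divided by 1000 so that the
#'     conventional high-confidence cut of 700 becomes 0.7.}
#' }
#' Self-loop rows and duplicate unordered pairs are dropped; the number
#' dropped is reported via [message()].
#'
#' @param path path to the edge file.
#' @param dialect `"generic"` or `"string_links"`.
#' @return An `edge_table`: data frame with columns `node_a`, `node_b`,
#'   `score`, plus a `dialect` attribute.
#' @export
read_edge_table <- function(path, dialect = c("generic", "string_links")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge table not found: ", path)
  if (dialect == "generic") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "",
                             blank.lines.skip = FALSE)
    if (!all(c("node_a", "node_b") %in% names(raw))) {
      stop("generic edge table requires header columns node_a and node_b: ", path)
    }
    score <- if ("score" %in% names(raw)) {
      s <- suppressWarnings(as.numeric(raw$score))
      s[is.na(raw$score) | raw$score == ""] <- 1
      s
    } else rep(1, nrow(raw))
    bad <- which(is.na(score) | score < 0 | score > 1 |
                 is.na(raw$node_a) | raw$node_a == "" |
                 is.na(raw$node_b) | raw$node_b == "")
    if (length(bad) > 0) {
      stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
    }
    df <- data.frame(node_a = raw$node_a, node_b = raw$node_b, score = score,
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, header = TRUE, colClasses = "character",
                             quote = "", comment.char = "")
    if (!all(c("protein1", "protein2", "combined_score") %in% names(raw))) {
      stop("string_links table requires columns protein1, protein2, combined_score: ", path)
    }
    cs <- suppressWarnings(as.numeric(raw$combined_score))
    bad <- which(is.na(cs) | cs < 0 | cs > 1000 |
                 is.na(raw$protein1) | raw$protein1 == "" |
                 is.na(raw$protein2) | raw$protein2 == "")
    if (length(bad) > 0) {
      stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
    }
    df <- data.frame(node_a = raw$protein1, node_b = raw$protein2,
                     score = cs / 1000, stringsAsFactors = FALSE)
  }
  edge_table(df, dialect = dialect)
}

#' Construct an edge table from a data frame
#'
#' Canonicalizes an undirected edge list: self-loops are removed, (a, b) and
#' (b, a) are identified, and duplicate pairs are collapsed to their first
#' occurrence. Dropped row counts are reported via [message()].
#'
#' @param df data frame with columns `node_a`, `node_b` and optional `score`.
#' @param dialect provenance tag stored on the result.
#' @return An `edge_table` data frame (`node_a`, `node_b`, `score`).
#' @export
edge_table <- function(df, dialect = "generic") {
  stopifnot(all(c("node_a", "node_b") %in% names(df)))
  a <- as.character(df$node_a); b <- as.character(df$node_b)
  score <- as.numeric(df$score %||% rep(1, nrow(df)))
  stopifnot(all(score >= 0 & score <= 1))
  loops <- a == b
  if (any(loops)) message(sum(loops), " self-loop row(s) dropped")
  a2 <- a[!loops]; b2 <- b[!loops]; s2 <- score[!loops]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  dup <- duplicated(edge_key(lo, hi))
  if (any(dup)) message(sum(dup), " duplicate edge row(s) dropped")
  out <- data.frame(node_a = lo[!dup], node_b = hi[!dup], score = s2[!dup],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dialect") <- dialect
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Build a network from an edge table
#'
#' Retains rows with `score > min_score` (strictly greater, matching the
#' conventional STRING high-confidence cut "> 0.7") and forms the simple
#' undirected graph over the endpoints of the retained rows.
#'
#' @param edges an [edge_table()].
#' @param min_score confidence threshold in \[0, 1\]; strict.
#' @return A [ppi_network()]. An empty result is allowed (with a warning).
#' @export
build_network <- function(edges, min_score = 0.7) {
  stopifnot(is.numeric(min_score), min_score >= 0, min_score <= 1)
  keep <- edges$score > min_score
  if (!any(keep)) {
    warning("no edges exceed min_score = ", min_score, "; returning empty network")
    return(ppi_network(NULL))
  }
  ppi_network(edges[keep, , drop = FALSE])
}

#' Merge additional edges into an existing network
#'
#' Adds the rows of `extra` that pass the threshold to `base`. The node set
#' grows only by endpoints of admitted edges; confidences of edges already in
#' `base` are preserved (incoming duplicates are ignored).
#'
#' @param base a [ppi_network()].
#' @param extra an [edge_table()] of candidate edges.
#' @param min_score strict confidence threshold.
#' @return The merged [ppi_network()].
#' @export
merge_networks <- function(base, extra, min_score = 0.7) {
  stopifnot(inherits(base, "ppi_network"))
  admitted <- extra[extra$score > min_score, , drop = FALSE]
  cur <- network_edges(base)
  if (nrow(admitted) > 0) {
    novel <- !(edge_key(admitted$node_a, admitted$node_b) %in%
               edge_key(cur$node_a, cur$node_b))
    admitted <- admitted[novel, , drop = FALSE]
  }
  all_edges <- rbind(
    data.frame(node_a = cur$node_a, node_b = cur$node_b, score = cur$confidence,
               stringsAsFactors = FALSE),
    data.frame(node_a = admitted$node_a, node_b = admitted$node_b,
               score = admitted$score, stringsAsFactors = FALSE))
  ppi_network(all_edges, nodes = network_nodes(base))
}

#' Expand a network by connectivity-ranked node addition
#'
#' Grows `base` from a pool of candidate edges, one node per ranking pass.
#' At each pass every external node is scored by (i) its number of admitted
#' edges (score > `min_score`) into the *current* network, (ii) the summed
#' confidence of those edges, and (iii) lexicographic symbol order as the
#' final tie-break; the top-ranked node is added together with all its
#' admitted edges. Because the network grows between passes, edges among
#' newly admitted nodes are picked up automatically.
#'
#' @param base a [ppi_network()].
#' @param pool an [edge_table()] of candidate edges (may reference external
#'   nodes).
#' @param n_add number of nodes to add (>= 0).
#' @param min_score strict confidence threshold for admitting pool edges.
#' @return The expanded [ppi_network()]. If the pool is exhausted early the
#'   partially expanded network is returned with a warning.
#' @export
expand_network <- function(base, pool, n_add, min_score = 0.7) {
  stopifnot(inherits(base, "ppi_network"), n_add >= 0)
  if (n_add == 0) return(base)
  admitted <- pool[pool$score > min_score, , drop = FALSE]
  cur <- network_edges(base)
  edges <- data.frame(node_a = cur$node_a, node_b = cur$node_b,
                      score = cur$confidence, stringsAsFactors = FALSE)
  nodes <- network_nodes(base)
  for (step in seq_len(n_add)) {
    a_in <- admitted$node_a %in% nodes
    b_in <- admitted$node_b %in% nodes
    linking <- xor(a_in, b_in)
    if (!any(linking)) {
      warning("pool exhausted after adding ", step - 1L, " of ", n_add, " nodes")
      break
    }
    ext <- ifelse(a_in[linking], admitted$node_b[linking], admitted$node_a[linking])
    links <- tapply(admitted$score[linking], ext, length)
    sums <- tapply(admitted$score[linking], ext, sum)
    cand <- names(links)
    ord <- order(-as.numeric(links), -as.numeric(sums), cand)
    best <- cand[ord[1]]
    nodes <- c(nodes, best)
    pick <- linking & (admitted$node_a == best | admitted$node_b == best)
    edges <- rbind(edges, admitted[pick, c("node_a", "node_b", "score")])
    admitted <- admitted[!pick, , drop = FALSE]
  }
  ppi_network(edges, nodes = nodes)
}

#' Write a network edge list to TSV
#'
#' Writes columns `node_a`, `node_b`, `score` (the stored confidence) so the
#' file round-trips through [read_edge_table()] with the generic dialect.
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  df <- network_edges(net)
  names(df) <- c("node_a", "node_b", "score")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by [write_network_tsv()]
#'
#' @param path TSV path with columns `node_a`, `node_b`, `score`.
#' @return A [ppi_network()] containing every row (no thresholding).
#' @export
read_network_tsv <- function(path) {
  ppi_network(read_edge_table(path, dialect = "generic"))
}
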