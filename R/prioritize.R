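#' Label seed (EMT) genes on a network
#'
#' Tags the intersection of `seed_genes` and the network's nodes with
#' `"EMT"`. Matching is exact and case-sensitive; the number of seed symbols
#' absent from the network is reported via [message()].
#'
#' @param net a [ppi_network()].
#' @param seed_genes character vector of seed gene symbols.
#' @return The network with tagged seeds.
#' @export
label_seeds <- function(net, seed_genes) {
  stopifnot(inherits(net, "ppi_network"), is.character(seed_genes))
  present <- intersect(seed_genes, network_nodes(net))
  missing <- setdiff(seed_genes, present)
  if (length(present) == 0) {
    stop("no seed genes found in the network; prioritization cannot proceed")
  }
  if (length(missing) > 0) {
    message(length(missing), " seed symbol(s) not present in the network")
  }
  tag_nodes(net, present, "EMT")
}

#' Extract candidate genes: immediate neighbours of the seed set
#'
#' Candidates are the union of neighbours of EMT-tagged nodes, minus the
#' EMT nodes themselves. For each candidate the table records its
#' connectivity to seed genes (`emt_connectivity`) and its overall degree.
#'
#' @param net a [ppi_network()] with at least one `"EMT"`-tagged node (see
#'   [label_seeds()]).
#' @return A `candidate_table` data frame with columns `symbol`,
#'   `emt_connectivity`, `total_degree`, `status` (all `"candidate"`).
#' @export
find_candidates <- function(net) {
  seeds <- nodes_with_tag(net, "EMT")
  if (length(seeds) == 0) stop("no EMT-tagged nodes; run label_seeds() first")
  g <- net$graph
  nbr_idx <- unique(unlist(igraph::ego(g, order = 1, nodes = seeds, mindist = 1)))
  cand <- sort(setdiff(igraph::V(g)$name[nbr_idx], seeds))
  deg <- igraph::degree(g)
  emt_conn <- vapply(cand, function(v) {
    sum(igraph::V(g)$name[igraph::neighbors(g, v)] %in% seeds)
  }, numeric(1))
  out <- data.frame(symbol = cand,
                    emt_connectivity = as.numeric(emt_conn),
                    total_degree = as.numeric(deg[cand]),
                    status = rep("candidate", length(cand)),
                    doids = rep("", length(cand)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Annotation filter: remove candidates with prior cancer annotation
#'
#' Marks a candidate `removed_annotation` when any of its Disease Ontology
#' term names or slim tags contains any of the keywords (case-insensitive
#' substring match). Candidates absent from the map are retained: the filter
#' removes only genes with documented prior cancer links, because their
#' association with the seed phenotype is not novel.
#'
#' @param cands a `candidate_table` from [find_candidates()].
#' @param doid_map data frame with columns `gene`, `doid`, `term_name`,
#'   `slim` (one row per gene-term pair).
#' @param keywords non-empty character vector of cancer-related keywords.
#' @return The updated `candidate_table`; matched DO terms are recorded in
#'   the `doids` column.
#' @export
annotation_filter <- function(cands, doid_map,
                              keywords = c("glioma", "cancer", "tumor",
                                           "cancer_DO_slim")) {
  stopifnot(inherits(cands, "candidate_table"), length(keywords) > 0)
  stopifnot(all(c("gene", "term_name") %in% names(doid_map)))
  slim <- doid_map$slim %||% rep("", nrow(doid_map))
  kw <- tolower(keywords)
  for (i in which(cands$status == "candidate")) {
    rows <- which(doid_map$gene == cands$symbol[i])
    if (length(rows) == 0) next
    text <- tolower(c(doid_map$term_name[rows], slim[rows]))
    hit <- any(vapply(kw, function(k) any(grepl(k, text, fixed = TRUE)),
                      logical(1)))
    cands$doids[i] <- paste(unique(doid_map$term_name[rows]), collapse = "; ")
    if (hit) cands$status[i] <- "removed_annotation"
  }
  cands
}

#' Connectivity filter: remove degree-explained candidates
#'
#' A candidate can neighbour many seed genes simply because it is highly
#' connected overall. This filter fits a local (loess) regression of
#' `emt_connectivity` on `total_degree` over the surviving candidates and
#' eliminates those whose connectivity lies *within* the pointwise
#' confidence band `fit +/- z(ci_level) * SE`, i.e. those consistent with
#' the degree-explained trend. Survivors (outliers relative to the band)
#' are marked `final`.
#'
#' @param cands a `candidate_table` with >= 10 candidates still in status
#'   `"candidate"`.
#' @param span loess span (local polynomial degree 2).
#' @param ci_level confidence level of the elimination band.
#' @param keep `"both"` retains outliers on either side of the band;
#'   `"above"` retains only candidates with excess seed connectivity.
#' @return The updated `candidate_table` with statuses
#'   `removed_connectivity` / `final`.
#' @export
connectivity_filter <- function(cands, span = 0.75, ci_level = 0.95,
                                keep = c("both", "above")) {
  stopifnot(inherits(cands, "candidate_table"))
  keep <- match.arg(keep)
  active <- which(cands$status == "candidate")
  if (length(active) < 10) {
    stop("connectivity filter needs at least 10 surviving candidates, got ",
         length(active))
  }
  x <- cands$total_degree[active]
  y <- cands$emt_connectivity[active]
  if (length(unique(x)) < 2) {
    stop("degenerate degree range: all candidates share one total_degree, ",
         "loess fit is undefined")
  }
  fit <- tryCatch(
    suppressWarnings(stats::loess(y ~ x, span = span, degree = 2)),
    error = function(e) stop("loess fit failed: ", conditionMessage(e)))
  pred <- suppressWarnings(stats::predict(fit, se = TRUE))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  resid <- y - pred$fit
  inside <- abs(resid) <= z * pred$se.fit + 1e-8
  survives <- if (keep == "both") !inside else (!inside & resid > 0)
  cands$status[active[!survives]] <- "removed_connectivity"
  cands$status[active[survives]] <- "final"
  cands
}

#' Write / read candidate tables
#'
#' Plain TSV round-trip of a `candidate_table`, preserving filter provenance
#' (`status`) for downstream hit calling.
#'
#' @param cands a `candidate_table`.
#' @param path file path.
#' @return `write_candidate_table()` returns `path` invisibly;
#'   `read_candidate_table()` the table.
#' @export
write_candidate_table <- function(cands, path) {
  utils::write.table(cands, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(symbol = "character",
                                               status = "character"))
  df$doids <- as.character(df$doids %||% rep("", nrow(df)))
  class(df) <- c("candidate_table", "data.frame")
  df
}
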