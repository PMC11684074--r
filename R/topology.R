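#' Topological summary of a network
#'
#' Computes the scalar metrics used to track a network expansion series:
#' density \eqn{2E/(N(N-1))}, mean degree \eqn{2E/N}, global mean local
#' clustering coefficient (nodes of degree < 2 contribute 0), and the
#' characteristic path length. The CPL is reported in *intermediate-node*
#' units: the mean over connected node pairs of (shortest-path edge count
#' - 1), i.e. the average number of nodes traversed between two endpoints;
#' two adjacent proteins are 0 apart, two proteins bridged by one shared
#' effector are 1 apart. The conventional edge-count CPL is also exported
#' as `cpl_edges`. Both are computed within the largest connected component
#' (distances between disconnected pairs are undefined).
#'
#' A power-law exponent (via [fit_power_law()]) and kneedle hub set (via
#' [detect_hubs()]) are attached when the network supports them, `NA`/empty
#' otherwise.
#'
#' @param net a [ppi_network()] with at least 2 nodes.
#' @param sensitivity kneedle sensitivity passed to [detect_hubs()].
#' @return A `topology_summary` list.
#' @export
topology_summary <- function(net, sensitivity = 1) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n < 2) stop("topology summary requires at least 2 nodes")
  density <- 2 * e / (n * (n - 1))
  avg_neighbours <- 2 * e / n
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- mean(local_cc)
  comp <- igraph::components(g)
  giant_ids <- which(comp$membership == which.max(comp$csize))
  cpl_edges <- NA_real_
  if (length(giant_ids) >= 2) {
    giant <- igraph::induced_subgraph(g, giant_ids)
    cpl_edges <- igraph::mean_distance(giant, directed = FALSE)
  }
  gamma <- tryCatch(fit_power_law(table(igraph::degree(g))),
                    error = function(e) NA_real_)
  hubs <- tryCatch(suppressWarnings(detect_hubs(net, sensitivity = sensitivity)),
                   error = function(e) list(hubs = character(0), elbow_k = NA_real_))
  structure(list(n_nodes = n, n_edges = e, density = density,
                 avg_neighbours = avg_neighbours, clustering = clustering,
                 cpl = cpl_edges - 1, cpl_edges = cpl_edges,
                 gamma = gamma, hubs = hubs$hubs, elbow_k = hubs$elbow_k),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary> N = %d, E = %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density %.4f  <k> %.2f  clustering %.4f\n",
              x$density, x$avg_neighbours, x$clustering))
  cat(sprintf("  CPL %.3f intermediate nodes (%.3f edges)  gamma %.3f\n",
              x$cpl, x$cpl_edges, x$gamma))
  cat(sprintf("  hubs: %d (elbow degree %s)\n", length(x$hubs),
              format(x$elbow_k)))
  invisible(x)
}

#' Number of intermediate nodes on a shortest path
#'
#' Shortest-path length between two nodes measured in intermediate nodes
#' (edge count - 1); adjacent nodes are 0 apart.
#'
#' @param net a [ppi_network()].
#' @param from,to node symbols.
#' @return Non-negative count, or `Inf` if disconnected.
#' @export
shortest_path_intermediates <- function(net, from, to) {
  g <- net$graph
  stopifnot(from %in% igraph::V(g)$name, to %in% igraph::V(g)$name)
  d <- igraph::distances(g, v = from, to = to)[1, 1]
  if (is.infinite(d)) return(Inf)
  d - 1
}

#' Fit a power-law exponent to a degree distribution
#'
#' Ordinary least squares on (log10 k, log10 count) over the nonzero entries
#' with k >= 1; the exponent is the negated slope of the fit, matching the
#' form \eqn{p(k) = k^{-\gamma}}. A transparent regression-style fit on the
#' degree plot, not a maximum-likelihood tail estimator.
#'
#' @param degree_distribution a [table()] or named vector mapping degree k
#'   to the number of nodes with that degree.
#' @return The fitted exponent gamma.
#' @export
fit_power_law <- function(degree_distribution) {
  k <- as.numeric(names(degree_distribution))
  cnt <- as.numeric(degree_distribution)
  keep <- !is.na(k) & k >= 1 & cnt > 0
  if (sum(keep) < 3) stop("power-law fit needs at least 3 distinct degrees >= 1")
  lk <- log10(k[keep]); lc <- log10(cnt[keep])
  fit <- stats::lm(lc ~ lk)
  -unname(stats::coef(fit)[2])
}

# kneedle on a normalized curve already transformed to concave-increasing
# form; returns the index of the knee or NA when no point satisfies the
# sensitivity threshold
kneedle_index <- function(y_norm, sensitivity) {
  n <- length(y_norm)
  x_norm <- (seq_len(n) - 1) / (n - 1)
  d <- y_norm - x_norm
  i <- which.max(d)
  threshold <- d[i] - sensitivity * mean(diff(x_norm))
  if (i <= 1 || !any(d[i:n] < threshold)) return(NA_integer_)
  i
}

#' Detect hub nodes via the kneedle elbow of the degree plot
#'
#' Sorts nodes by descending degree, locates the elbow of the rank-vs-degree
#' curve with the kneedle algorithm (curve normalized to the unit square and
#' transformed from its convex-decreasing orientation; the elbow is the
#' maximum of the difference curve, accepted only if the curve later falls
#' `sensitivity` mean-spacings below that maximum), and returns the nodes
#' ranked before the elbow as hubs. Nodes tied with the last included hub
#' degree are all included, so the hub set is a clean degree cut.
#'
#' @param net a [ppi_network()] with >= 5 nodes.
#' @param sensitivity kneedle sensitivity (> 0); larger is more conservative.
#' @return List with `hubs` (character vector, possibly empty) and `elbow_k`
#'   (degree at the elbow; `NA` when no knee is detected).
#' @export
detect_hubs <- function(net, sensitivity = 1) {
  stopifnot(inherits(net, "ppi_network"), sensitivity > 0)
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 5) stop("hub detection requires at least 5 nodes")
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  y <- as.numeric(deg[ord])
  if (max(y) == min(y)) {
    warning("flat degree curve: no elbow, empty hub set")
    return(list(hubs = character(0), elbow_k = NA_real_))
  }
  yt <- max(y) - y                      # convex-decreasing -> concave-increasing
  i <- kneedle_index(yt / max(yt), sensitivity)
  if (is.na(i)) {
    warning("no detectable knee on the degree curve; empty hub set")
    return(list(hubs = character(0), elbow_k = NA_real_))
  }
  cutoff <- y[i - 1]                    # degree of the last node before the elbow
  hubs <- names(deg)[deg >= cutoff]
  list(hubs = sort(hubs), elbow_k = y[i])
}
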