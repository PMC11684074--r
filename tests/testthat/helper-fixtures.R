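# toy graphs and independent oracles used across test files

make_path <- function(n) {
  syms <- LETTERS[seq_len(n)]
  ppi_network(data.frame(node_a = syms[-n], node_b = syms[-1]))
}

make_cycle <- function(n) {
  syms <- LETTERS[seq_len(n)]
  ppi_network(data.frame(node_a = syms, node_b = c(syms[-1], syms[1])))
}

make_complete <- function(n) {
  syms <- LETTERS[seq_len(n)]
  pairs <- t(utils::combn(syms, 2))
  ppi_network(data.frame(node_a = pairs[, 1], node_b = pairs[, 2]))
}

make_star <- function(n_leaves, center = "C0") {
  ppi_network(data.frame(node_a = rep(center, n_leaves),
                         node_b = paste0("L", seq_len(n_leaves))))
}

# the two-Rab / two-effector worked example
make_rab_toy <- function() {
  ppi_network(data.frame(
    node_a = c("RAB19", "RAB19", "RAB6A", "RAB6A", "GOLGA1"),
    node_b = c("GOLGA1", "GCC1", "GOLGA1", "GCC1", "GCC1")))
}

# exhaustive oracle: entropy statistics over ALL removal sets of round(f*N)
# nodes, computed directly from component enumeration (independent of the
# Monte-Carlo path under test)
exhaustive_entropy <- function(net, f) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  k <- round(f * n)
  if (k == 0) {
    vals <- component_entropy(igraph::components(g)$csize, n)
  } else if (k >= n) {
    vals <- 1
  } else {
    sets <- utils::combn(n, k)
    vals <- apply(sets, 2, function(drop) {
      comp <- igraph::components(igraph::delete_vertices(g, drop))
      component_entropy(comp$csize, n)
    })
  }
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n_sets = length(vals))
}

# independent kneedle oracle: argmax of the normalized difference curve on a
# descending-degree sequence (after the convex-decreasing transform)
kneedle_oracle_index <- function(degrees) {
  y <- sort(degrees, decreasing = TRUE)
  n <- length(y)
  xn <- (seq_len(n) - 1) / (n - 1)
  yt <- max(y) - y
  yn <- yt / max(yt)
  which.max(yn - xn)
}

# log-log regression oracle for the power-law exponent
gamma_oracle <- function(degrees) {
  tab <- table(degrees)
  k <- as.numeric(names(tab)); cnt <- as.numeric(tab)
  keep <- k >= 1 & cnt > 0
  fit <- stats::lm(log10(cnt[keep]) ~ log10(k[keep]))
  -unname(coef(fit)[2])
}
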