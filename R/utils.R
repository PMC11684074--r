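# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-stream seeds; kept below 2^31 - 1
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

# composite trapezoidal rule on an ordered grid
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# canonical key for an undirected edge
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
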