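#' Canonicalize a node walk into an anonymous walk
#'
#' Replaces node identities by order of first appearance, starting at 1:
#' two walks that visit different nodes in the same revisit structure map
#' to the same pattern, which is what makes the embedding invariant to
#' node relabeling.
#'
#' @param node_sequence vector of node labels visited in order.
#' @return Integer vector: the anonymous pattern (first element always 1).
#' @examples
#' canonicalize_walk(c("Fp1", "F3", "Fp1", "C3"))  # 1 2 1 3
#' @export
canonicalize_walk <- function(node_sequence) {
  if (length(node_sequence) == 0L) {
    cw_stop("coherwalk_domain_error", "empty walk")
  }
  if (length(node_sequence) > 1L &&
      any(node_sequence[-1L] == node_sequence[-length(node_sequence)])) {
    cw_stop("coherwalk_domain_error",
            "walk repeats a node consecutively (graphs have no self-loops)")
  }
  as.integer(match(node_sequence, unique(node_sequence)))
}

pattern_key <- function(p) paste(p, collapse = "-")

#' Enumerate all anonymous walks of a given length
#'
#' Generates every anonymous-walk pattern of length `l` (counted in
#' edges; a pattern has `l + 1` elements) exactly once, in lexicographic
#' order. This fixed ordering indexes embedding vectors consistently
#' across graphs and runs. The vocabulary size grows steeply with `l`:
#' 1, 2, 5, 15, 52, 203, 877 for l = 1..7.
#'
#' @param l walk length in edges (>= 1; capped at 12).
#' @return An object of class `walk_index`: `length`, `patterns` (list of
#'   integer vectors), `keys` (pattern strings like "1-2-1-3"), `size`.
#' @export
enumerate_walks <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l != round(l)) {
    cw_stop("coherwalk_domain_error", "walk length l must be an integer >= 1")
  }
  if (l > 12) cw_stop("coherwalk_domain_error", "l > 12 not supported")
  patterns <- cpp_enumerate_walks(as.integer(l))
  structure(list(length = as.integer(l), patterns = patterns,
                 keys = vapply(patterns, pattern_key, character(1)),
                 size = length(patterns)),
            class = "walk_index")
}

#' @export
print.walk_index <- function(x, ...) {
  cat(sprintf("<walk_index> length %d: %d patterns\n", x$length, x$size))
  invisible(x)
}

#' Monte-Carlo sample-size bound for the walk distribution
#'
#' Minimum number of random walks m so that the empirical anonymous-walk
#' distribution deviates from the exact one by more than epsilon (in L1)
#' with probability at most delta:
#' m = ceil( (2 / eps^2) (ln(2^N - 2) - ln delta) ),
#' where N is the vocabulary size. For large N the first logarithm is
#' evaluated stably as N ln 2 + log1p(-2^(1-N)). Natural logarithms; the
#' result is rounded up because the bound is a minimum.
#'
#' @param N number of anonymous-walk patterns (>= 2).
#' @param epsilon L1 approximation error bound (> 0); default 0.1.
#' @param delta failure probability (in (0,1)); default 0.01.
#' @return Integer m. For N = 52 (walk length 5), the defaults give 8130.
#' @export
required_walk_count <- function(N, epsilon = 0.1, delta = 0.01) {
  if (N < 2) {
    cw_stop("coherwalk_domain_error",
            "N must be >= 2 (2^N - 2 must be positive)")
  }
  if (epsilon <= 0 || delta <= 0 || delta >= 1) {
    cw_stop("coherwalk_domain_error", "require epsilon > 0 and 0 < delta < 1")
  }
  log_card <- N * log(2) + log1p(-2^(1 - N))  # ln(2^N - 2), stable for large N
  as.integer(ceiling((2 / epsilon^2) * (log_card - log(delta))))
}

#' Sampling plan for Monte-Carlo walk embeddings
#'
#' @param l walk length (used to look up the vocabulary size N).
#' @param epsilon,delta accuracy / failure-probability parameters of
#'   [required_walk_count()]; defaults 0.1 and 0.01.
#' @param m number of walks; defaults to the bound.
#' @return An object of class `sampling_plan` with fields `epsilon`,
#'   `delta`, `m`, `N`, `l`.
#' @export
sampling_plan <- function(l, epsilon = 0.1, delta = 0.01, m = NULL) {
  N <- enumerate_walks(l)$size
  if (is.null(m)) m <- required_walk_count(N, epsilon, delta)
  if (m < 1) cw_stop("coherwalk_domain_error", "m must be >= 1")
  structure(list(epsilon = epsilon, delta = delta, m = as.integer(m),
                 N = N, l = as.integer(l)),
            class = "sampling_plan")
}

new_walk_embedding <- function(probabilities, index, m = NA_integer_,
                               seed = NA_integer_) {
  names(probabilities) <- index$keys
  structure(list(probabilities = probabilities, length = index$length,
                 size = index$size, m = m, seed = seed),
            class = "walk_embedding")
}

#' @export
print.walk_embedding <- function(x, ...) {
  cat(sprintf("<walk_embedding> l = %d, %d patterns, %s\n", x$length, x$size,
              if (is.na(x$m)) "exact" else sprintf("sampled (m = %d, seed = %s)",
                                                   x$m, x$seed)))
  invisible(x)
}

check_walkable <- function(g) {
  stopifnot(inherits(g, "electrode_graph"))
  if (n_edges(g) == 0L) {
    cw_stop("coherwalk_no_walk_error",
            "graph has no edges: walk distribution undefined")
  }
}

#' Exact anonymous-walk embedding of a graph
#'
#' Brute-force oracle: accumulates the probability of every node walk of
#' length `l` (start uniform over nodes of degree >= 1, each step uniform
#' over neighbors) onto its anonymous pattern. The result is the exact
#' distribution the Monte-Carlo estimator converges to; it is invariant
#' under node permutations and sums to 1.
#'
#' Cost grows as roughly |V| * max_degree^l; intended for the 16-node
#' electrode graphs and moderate l (<= 6), and as the ground truth
#' against which [sample_embedding()] is validated.
#'
#' @param g an [electrode_graph()] with at least one edge.
#' @param l walk length in edges.
#' @return A `walk_embedding` (probability vector over the `walk_index`
#'   ordering of patterns).
#' @export
exact_embedding <- function(g, l) {
  check_walkable(g)
  index <- enumerate_walks(l)
  A <- g$adjacency
  storage.mode(A) <- "integer"
  probs <- cpp_exact_embedding(A, index$length, index$patterns)
  new_walk_embedding(probs, index)
}

#' Sampled anonymous-walk embedding of a graph
#'
#' Performs `plan$m` independent random walks (uniform start over
#' degree->=1 nodes, uniform neighbor steps, immediate backtracking
#' allowed), canonicalizes each, and returns the empirical pattern
#' frequencies. With `m` from [required_walk_count()] the L1 distance to
#' the exact distribution exceeds epsilon with probability at most delta.
#'
#' @param g an [electrode_graph()] with at least one edge.
#' @param l walk length in edges.
#' @param plan a [sampling_plan()]; defaults to the bound at
#'   epsilon = 0.1, delta = 0.01 for this `l`.
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return A `walk_embedding` of empirical frequencies (sums to 1
#'   exactly; each entry is a multiple of 1/m).
#' @export
sample_embedding <- function(g, l, plan = sampling_plan(l), seed = NULL) {
  check_walkable(g)
  if (plan$l != l) {
    cw_stop("coherwalk_config_error",
            "sampling plan was built for l = %d, not l = %d", plan$l, l)
  }
  index <- enumerate_walks(l)
  A <- g$adjacency
  storage.mode(A) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  counts <- cpp_sample_walks(A, index$length, plan$m, index$patterns)
  new_walk_embedding(counts / plan$m, index, m = plan$m,
                     seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
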