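#' Node centrality measures
#'
#' The three centralities used for influential-spreader identification:
#' degree (local), k-core decomposition (global placement) and exact
#' shortest-path betweenness (global). `k_core()` returns each node's
#' core number, the largest k such that the node belongs to a maximal
#' subgraph of minimum degree >= k. Betweenness uses the unordered-pair
#' convention on undirected graphs (the centre of a 5-node star scores
#' choose(4, 2) = 6); pairs in different components contribute nothing.
#'
#' Exact algorithms are used throughout — an approximation would
#' contaminate the comparison between sample-based and full-information
#' rankings.
#'
#' @param graph An undirected igraph graph.
#' @return A named numeric (or integer) vector of scores, one per node.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' degree_centrality(g)
#' betweenness_centrality(g)
#' @name centrality
NULL

#' @rdname centrality
#' @export
degree_centrality <- function(graph) {
  graph <- as_maxrd_graph(graph)
  deg <- igraph::degree(graph)
  stats::setNames(as.integer(deg), igraph::V(graph)$name)
}

#' @rdname centrality
#' @export
k_core <- function(graph) {
  graph <- as_maxrd_graph(graph)
  stats::setNames(as.integer(igraph::coreness(graph)),
                  igraph::V(graph)$name)
}

#' @rdname centrality
#' @export
betweenness_centrality <- function(graph) {
  graph <- as_maxrd_graph(graph)
  stats::setNames(igraph::betweenness(graph, directed = FALSE),
                  igraph::V(graph)$name)
}

centrality_function <- function(measure) {
  switch(measure,
         degree = degree_centrality,
         kcore = k_core,
         betweenness = betweenness_centrality,
         stop("unknown centrality measure: ", measure, call. = FALSE))
}

#' Rank nodes by score, breaking ties at random
#'
#' Orders nodes by descending score. Nodes with equal scores are shuffled
#' uniformly at random within their tie group using the given seed, so
#' rankings are reproducible while avoiding any systematic id-order bias.
#' Tie handling matters here because k-core (and, on samples, degree)
#' scores tie heavily, which directly affects which nodes enter a top-k
#' set.
#'
#' @param scores Named numeric vector, one score per node.
#' @param rng_seed Integer seed for the tie-breaking shuffle.
#' @return An object of class `ranked_list`: a list with
#'   `ordered_nodes` (best first), `scores` and `tie_policy`.
#' @examples
#' rank_nodes(c(a = 3, b = 1, c = 2), rng_seed = 1)$ordered_nodes
#' @export
rank_nodes <- function(scores, rng_seed = 1L) {
  if (is.null(names(scores)) || anyNA(scores)) {
    stop("'scores' must be a named vector without missing values",
         call. = FALSE)
  }
  ord <- with_rng(rng_seed,
                  order(-as.numeric(scores), sample.int(length(scores))))
  structure(list(ordered_nodes = names(scores)[ord],
                 scores = scores,
                 tie_policy = "seeded_random_shuffle",
                 rng_seed = as.integer(rng_seed)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  n <- length(x$ordered_nodes)
  cat(sprintf("<ranked_list> %d nodes, tie policy: %s\n", n, x$tie_policy))
  show <- head(x$ordered_nodes, 5L)
  cat("  top:", paste(show, collapse = ", "),
      if (n > 5L) "..." else "", "\n")
  invisible(x)
}

#' Top-k prefix of a ranked list
#'
#' @param ranking A `ranked_list`.
#' @param k Number of nodes to take.
#' @return Character vector of the k best-ranked nodes.
#' @export
top_k_nodes <- function(ranking, k) {
  stopifnot(inherits(ranking, "ranked_list"))
  if (length(ranking$ordered_nodes) < k) {
    stop("ranking holds fewer than k = ", k, " nodes", call. = FALSE)
  }
  head(ranking$ordered_nodes, k)
}

#' Size of a top-k set
#'
#' Converts a top-k fraction (the reference grid is 1%, 2%, ..., 10%)
#' into a node count relative to the original graph's population,
#' rounding to the nearest integer with a floor of one node.
#'
#' @param fraction Top-k fraction in (0, 1].
#' @param population_size Number of nodes of the original graph.
#' @return Integer k.
#' @export
top_k_size <- function(fraction, population_size) {
  stopifnot(fraction > 0, fraction <= 1, population_size >= 1)
  max(1L, as.integer(round(fraction * population_size)))
}
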