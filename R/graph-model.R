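#' Read a whitespace-separated edge list into an undirected graph
#'
#' Parses the plain edge-list dialect used by large network repositories:
#' one edge per line as two whitespace-separated endpoint identifiers,
#' with `#`-prefixed comment lines. Directed input is symmetrized,
#' self-loops are dropped and parallel edges are collapsed, so the result
#' is always a simple undirected graph. Node identifiers are kept as
#' opaque strings; integer-looking ids are not coerced.
#'
#' @param path Path to the edge-list file, or a connection.
#' @param nodes Optional character vector of node ids. Ids not appearing
#'   in any edge are added as isolated vertices; an edge list alone never
#'   defines isolated nodes.
#' @return An undirected simple [igraph][igraph::igraph-package] graph
#'   with character vertex names.
#' @seealso [write_edge_list()], [graph_from_pairs()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy graph", "a b", "b a", "a a", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g) # 2: the duplicate and the self-loop are gone
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(graph_from_pairs(matrix(character(0), ncol = 2), nodes = nodes))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("malformed edge list: line ", idx[bad[1]],
         " has fewer than two fields", call. = FALSE)
  }
  pairs <- cbind(vapply(toks, `[[`, character(1), 1L),
                 vapply(toks, `[[`, character(1), 2L))
  graph_from_pairs(pairs, nodes = nodes)
}

#' Build a simple undirected graph from raw (possibly directed) pairs
#'
#' Every ordered pair (u, v) with u != v contributes the undirected edge
#' {u, v} exactly once; pairs (u, u) are dropped. This is the
#' symmetrize-and-clean preprocessing applied to directed source data.
#'
#' @param pairs Two-column character matrix (or data frame) of endpoint
#'   ids, one ordered pair per row.
#' @param nodes Optional character vector of additional (isolated) node
#'   ids.
#' @return An undirected simple igraph graph with character vertex names.
#' @examples
#' g <- graph_from_pairs(cbind(c("1", "2", "3"), c("2", "1", "3")))
#' igraph::ecount(g) # 1
#' @export
graph_from_pairs <- function(pairs, nodes = NULL) {
  pairs <- as.matrix(pairs)
  if (length(pairs) && ncol(pairs) != 2L) {
    stop("'pairs' must have two columns", call. = FALSE)
  }
  storage.mode(pairs) <- "character"
  verts <- unique(c(t(pairs), as.character(nodes)))
  if (nrow(pairs)) {
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  }
  if (nrow(pairs)) {
    key <- paste(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]), sep = "\r")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, rbind(match(pairs[, 1L], verts),
                                    match(pairs[, 2L], verts)))
  }
  g
}

#' Write a graph as a whitespace-separated edge list
#'
#' One line per undirected edge, each edge written once. Reading the file
#' back with [read_edge_list()] reproduces the same node and edge sets
#' (isolated nodes excepted, as the format cannot carry them).
#'
#' @param graph An undirected igraph graph.
#' @param path Output file path or connection.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  graph <- as_maxrd_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(if (nrow(el)) paste(el[, 1L], el[, 2L]) else character(0), path)
  invisible(path)
}

#' First and second moments of the degree distribution
#'
#' Computes the mean degree and mean squared degree of a graph. These two
#' moments determine the theoretical epidemic thresholds: see
#' [sir_threshold()] and [sis_threshold()]. Isolated vertices count with
#' degree zero.
#'
#' @param graph An undirected igraph graph with at least one vertex, or a
#'   numeric vector of degrees.
#' @return An object of class `degree_moments`: a list with elements
#'   `mean_degree` and `mean_squared_degree`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' degree_moments(g) # 8/5 and 20/5
#' @export
degree_moments <- function(graph) {
  deg <- if (igraph::is_igraph(graph)) {
    if (igraph::vcount(graph) == 0L) {
      stop("degree moments are undefined for the empty graph", call. = FALSE)
    }
    igraph::degree(as_maxrd_graph(graph))
  } else {
    as.numeric(graph)
  }
  if (!length(deg)) {
    stop("degree moments are undefined for the empty graph", call. = FALSE)
  }
  new_degree_moments(mean(deg), mean(deg^2))
}

new_degree_moments <- function(mean_degree, mean_squared_degree) {
  stopifnot(mean_degree >= 0, mean_squared_degree >= 0,
            mean_squared_degree >= mean_degree^2 - 1e-9)
  structure(list(mean_degree = mean_degree,
                 mean_squared_degree = mean_squared_degree),
            class = "degree_moments")
}

#' @export
print.degree_moments <- function(x, ...) {
  cat(sprintf("degree moments: <k> = %.4g, <k^2> = %.4g\n",
              x$mean_degree, x$mean_squared_degree))
  invisible(x)
}

# Coerce numeric pairs c(<k>, <k^2>) so the threshold formulas can be
# applied directly to published moment tables.
as_degree_moments <- function(x) {
  if (inherits(x, "degree_moments")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(new_degree_moments(x[1L], x[2L]))
  if (igraph::is_igraph(x)) return(degree_moments(x))
  stop("cannot interpret 'moments': give a degree_moments object, ",
       "a numeric pair c(mean, mean squared) or a graph", call. = FALSE)
}

# Normalize any igraph input to the package's working form: undirected,
# simple, character vertex names.
as_maxrd_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("'graph' must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

# Integer adjacency list (neighbour indices per vertex); the workhorse
# structure for the epidemic simulators and samplers.
adjacency_index <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}
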