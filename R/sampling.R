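#' Configuration shared by the graph samplers
#'
#' @param target_fraction Fraction of the original graph's nodes the
#'   sample must discover before the sampler halts (the sample size x;
#'   0.20 throughout the reference experiments).
#' @param seed_fraction Fraction of nodes drawn as initial seeds for the
#'   parallel traverses (1% for maxRD and MHRW in the reference setup).
#'   Exactly one of `seed_fraction` / `seed_count` may be given; when
#'   both are `NULL`, `seed_fraction = 0.01` is used.
#' @param seed_count Absolute number of initial seeds (Forest Fire uses
#'   1).
#' @param rng_seed Integer seed for the sampler's single RNG stream,
#'   recorded in the provenance.
#' @param p_forward Forward burning probability of Forest Fire, in
#'   (0, 1); default 0.7.
#' @param n_iterations Iteration budget for the Metropolis-Hastings
#'   degree-distribution sampler (20,000-30,000 in the reference setup).
#' @param initial_seeds Optional explicit vector of seed node names,
#'   overriding the random draw (useful for deterministic traces).
#' @param max_restarts Budget of random jumps / fire restarts before the
#'   sampler gives up with an error.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(target_fraction = 0.2,
                           seed_fraction = NULL,
                           seed_count = NULL,
                           rng_seed = 1L,
                           p_forward = 0.7,
                           n_iterations = 20000L,
                           initial_seeds = NULL,
                           max_restarts = 1000L) {
  if (!is.null(seed_fraction) && !is.null(seed_count)) {
    stop("give exactly one of 'seed_fraction' and 'seed_count'", call. = FALSE)
  }
  if (is.null(seed_fraction) && is.null(seed_count)) seed_fraction <- 0.01
  stopifnot(target_fraction > 0, target_fraction <= 1,
            is.null(seed_fraction) ||
              (seed_fraction > 0 && seed_fraction <= 1),
            is.null(seed_count) || seed_count >= 1,
            p_forward > 0, p_forward < 1,
            n_iterations >= 1, max_restarts >= 0)
  structure(list(target_fraction = target_fraction,
                 seed_fraction = seed_fraction,
                 seed_count = if (is.null(seed_count)) NULL
                              else as.integer(seed_count),
                 rng_seed = as.integer(rng_seed),
                 p_forward = p_forward,
                 n_iterations = as.integer(n_iterations),
                 initial_seeds = if (is.null(initial_seeds)) NULL
                                 else as.character(initial_seeds),
                 max_restarts = as.integer(max_restarts)),
            class = "sampler_config")
}

# Number of initial seeds for a graph of n nodes.
n_seeds <- function(config, n) {
  if (!is.null(config$seed_count)) return(min(n, config$seed_count))
  max(1L, as.integer(round(config$seed_fraction * n)))
}

target_size <- function(config, n) {
  k <- as.integer(ceiling(config$target_fraction * n))
  if (k < 1L) stop("target sample size below one node", call. = FALSE)
  k
}

initial_seed_idx <- function(config, graph, n) {
  if (!is.null(config$initial_seeds)) {
    idx <- match(config$initial_seeds, igraph::V(graph)$name)
    if (anyNA(idx)) stop("unknown initial seed node", call. = FALSE)
    return(as.integer(idx))
  }
  sample.int(n, n_seeds(config, n))
}

new_graph_sample <- function(algorithm, graph, crossed_idx, discovered_idx,
                             config, n_jumps) {
  nm <- igraph::V(graph)$name
  crossed <- if (length(crossed_idx)) {
    cbind(nm[crossed_idx[, 1L]], nm[crossed_idx[, 2L]])
  } else {
    matrix(character(0), ncol = 2)
  }
  structure(list(algorithm = algorithm,
                 crossed_edges = crossed,
                 discovered_nodes = nm[discovered_idx],
                 config = config,
                 rng_seed = config$rng_seed,
                 n_jumps = n_jumps),
            class = "graph_sample")
}

#' @export
print.graph_sample <- function(x, ...) {
  cat(sprintf("<graph_sample> %s: %d nodes discovered, %d edges crossed, %d random jumps (rng_seed %d)\n",
              x$algorithm, length(x$discovered_nodes),
              nrow(x$crossed_edges), x$n_jumps, x$rng_seed))
  invisible(x)
}

#' maxRD: rank-degree graph exploration sampling
#'
#' Explores a graph by s parallel traverses with a deterministic
#' selection rule: each current seed crosses the edge to its
#' maximum-residual-degree neighbour, the crossed edge is removed from a
#' working copy of the graph (visited nodes stay), and the selected
#' neighbours form the next seed set. Because crossed edges are deleted,
#' the degree ranking evolves as the exploration proceeds ("residual"
#' degree). When no current seed has any remaining incident edge the
#' sampler performs a random jump to fresh seeds. It halts once the
#' number of discovered nodes reaches the target size and returns the set
#' of crossed edges.
#'
#' Ties between equally ranked neighbours are broken uniformly at random
#' from the sampler's seeded RNG, so a run is fully reproducible given
#' `config$rng_seed`.
#'
#' @param graph An undirected igraph graph.
#' @param config A [sampler_config()].
#' @return An object of class `graph_sample` with fields
#'   `crossed_edges` (two-column character matrix), `discovered_nodes`,
#'   `algorithm`, `config`, `rng_seed` and `n_jumps`.
#' @references The rank-degree family of exploration samplers; this is
#'   the max-degree-neighbour variant.
#' @export
sample_max_rank_degree <- function(graph, config = sampler_config()) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot sample an empty graph", call. = FALSE)
  target <- target_size(config, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  m <- nrow(el)
  inc <- vector("list", n)                # incident edge ids per vertex
  if (m) {
    inc_all <- split(rep(seq_len(m), 2L), c(el[, 1L], el[, 2L]))
    inc[as.integer(names(inc_all))] <- inc_all
  }
  inc[vapply(inc, is.null, logical(1))] <- list(integer(0))
  alive <- rep(TRUE, m)
  resdeg <- tabulate(el, nbins = n)

  with_rng(config$rng_seed, {
    seeds <- initial_seed_idx(config, graph, n)
    discovered <- logical(n)
    discovered[seeds] <- TRUE
    crossed <- integer(0)
    jumps <- 0L
    while (sum(discovered) < target) {
      nxt <- integer(0)
      for (i in seeds) {
        eids <- inc[[i]]
        eids <- eids[alive[eids]]
        if (!length(eids)) next
        nbrs <- el[eids, 1L] + el[eids, 2L] - i
        rd <- resdeg[nbrs]
        best <- which(rd == max(rd))
        pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
        e <- eids[pick]
        j <- nbrs[pick]
        alive[e] <- FALSE
        resdeg[el[e, 1L]] <- resdeg[el[e, 1L]] - 1L
        resdeg[el[e, 2L]] <- resdeg[el[e, 2L]] - 1L
        crossed <- c(crossed, e)
        discovered[j] <- TRUE
        nxt <- c(nxt, j)
      }
      if (length(nxt)) {
        seeds <- unique(nxt)
      } else {
        # every current seed is exhausted in the working copy: random jump
        if (jumps >= config$max_restarts) {
          stop("maxRD: random-jump budget exhausted before reaching the ",
               "target sample size", call. = FALSE)
        }
        jumps <- jumps + 1L
        fresh <- which(!discovered)
        seeds <- fresh[sample.int(length(fresh),
                                  min(length(fresh), n_seeds(config, n)))]
        discovered[seeds] <- TRUE
      }
    }
    new_graph_sample("maxrd", graph, el[crossed, , drop = FALSE],
                     which(discovered), config, jumps)
  })
}

#' Forest Fire sampling
#'
#' From each node of the current frontier a geometrically distributed
#' number x of links to unburned neighbours is chosen uniformly at
#' random (all of them if fewer than x remain); the far endpoints become
#' the next frontier. Visited nodes are burned and never revisited. If
#' the fire dies before the target size is reached, it restarts from a
#' fresh unburned node. The geometric draw has mean
#' `p_forward / (1 - p_forward)` with support {0, 1, 2, ...}.
#'
#' @inheritParams sample_max_rank_degree
#' @return A `graph_sample`; see [sample_max_rank_degree()].
#' @export
sample_forest_fire <- function(graph, config = sampler_config(seed_count = 1)) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot sample an empty graph", call. = FALSE)
  target <- target_size(config, n)
  adj <- adjacency_index(graph)
  pf <- config$p_forward

  with_rng(config$rng_seed, {
    burned <- logical(n)
    frontier <- initial_seed_idx(config, graph, n)
    burned[frontier] <- TRUE
    crossed <- vector("list", 0L)
    restarts <- 0L
    while (sum(burned) < target) {
      nxt <- integer(0)
      for (w in frontier) {
        cand <- adj[[w]]
        cand <- cand[!burned[cand]]
        if (!length(cand)) next
        x <- rgeom(1L, prob = 1 - pf)   # mean pf / (1 - pf), support {0,1,...}
        if (x == 0L) next
        sel <- cand[sample.int(length(cand), min(x, length(cand)))]
        burned[sel] <- TRUE
        crossed[[length(crossed) + 1L]] <- cbind(w, sel)
        nxt <- c(nxt, sel)
      }
      if (length(nxt)) {
        frontier <- nxt
      } else {
        if (restarts >= config$max_restarts) {
          stop("forest fire: restart budget exhausted before reaching the ",
               "target sample size", call. = FALSE)
        }
        restarts <- restarts + 1L
        fresh <- which(!burned)
        frontier <- fresh[sample.int(length(fresh), 1L)]
        burned[frontier] <- TRUE
      }
    }
    crossed_idx <- if (length(crossed)) do.call(rbind, crossed)
                   else matrix(integer(0), ncol = 2)
    new_graph_sample("ff", graph, crossed_idx, which(burned), config, restarts)
  })
}

# One Metropolis-Hastings random-walk step from vertex x; returns the next
# position (y on acceptance, x on rejection, NA if x is isolated).
mhrw_step <- function(adj, deg, x) {
  nbrs <- adj[[x]]
  if (!length(nbrs)) return(NA_integer_)
  y <- nbrs[sample.int(length(nbrs), 1L)]
  if (runif(1L) <= deg[x] / deg[y]) y else x
}

#' Metropolis-Hastings random walk sampling
#'
#' Runs s parallel random walks whose proposed move x -> y (y a uniform
#' neighbour of x) is accepted with probability min(1, deg(x)/deg(y)),
#' with degrees taken in the original graph; this makes the walk's
#' stationary distribution uniform over nodes. Accepted traversed edges
#' are recorded as crossed; rejected proposals cross nothing. Walks that
#' get trapped simply stop contributing; a walk stranded on an isolated
#' node is re-drawn (counted as a jump). A global step budget of
#' `max_restarts * |N|` rounds guards against unreachable targets.
#'
#' @inheritParams sample_max_rank_degree
#' @return A `graph_sample`; see [sample_max_rank_degree()].
#' @export
sample_mhrw <- function(graph, config = sampler_config()) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot sample an empty graph", call. = FALSE)
  target <- target_size(config, n)
  adj <- adjacency_index(graph)
  deg <- igraph::degree(graph)

  with_rng(config$rng_seed, {
    pos <- initial_seed_idx(config, graph, n)
    discovered <- logical(n)
    discovered[pos] <- TRUE
    crossed <- vector("list", 0L)
    jumps <- 0L
    rounds <- 0L
    max_rounds <- max(1L, config$max_restarts) * n
    while (sum(discovered) < target) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("MHRW: step budget exhausted before reaching the target ",
             "sample size", call. = FALSE)
      }
      for (wi in seq_along(pos)) {
        x <- pos[wi]
        y <- mhrw_step(adj, deg, x)
        if (is.na(y)) {            # isolated start: re-draw this walk
          jumps <- jumps + 1L
          y <- sample.int(n, 1L)
          pos[wi] <- y
          discovered[y] <- TRUE
          next
        }
        if (y != x) {
          crossed[[length(crossed) + 1L]] <- c(x, y)
          pos[wi] <- y
          discovered[y] <- TRUE
        }
      }
    }
    crossed_idx <- if (length(crossed)) {
      mat <- do.call(rbind, crossed)
      mat[!duplicated(paste(pmin(mat[, 1L], mat[, 2L]),
                            pmax(mat[, 1L], mat[, 2L]))), , drop = FALSE]
    } else {
      matrix(integer(0), ncol = 2)
    }
    new_graph_sample("mhrw", graph, crossed_idx, which(discovered), config,
                     jumps)
  })
}

#' Metropolis-Hastings degree-distribution sampling
#'
#' A centralized sampler that takes the whole graph as input. It starts
#' from a uniform random node subset of the target size and, for a fixed
#' number of iterations, proposes swapping one in-sample node for one
#' out-of-sample node. The quality of a sample is the L1 distance between
#' the normalized degree histogram of its induced subgraph and that of
#' the original graph; a swap that lowers the distance is always
#' accepted, and a worsening swap is accepted with probability
#' `old_distance / new_distance`. The induced subgraph of the final node
#' set is returned as the sample.
#'
#' @inheritParams sample_max_rank_degree
#' @return A `graph_sample`; see [sample_max_rank_degree()].
#' @export
sample_metropolis_hastings <- function(graph, config = sampler_config()) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot sample an empty graph", call. = FALSE)
  size <- target_size(config, n)
  if (size > n) stop("target sample larger than the graph", call. = FALSE)
  adj <- adjacency_index(graph)
  deg <- igraph::degree(graph)
  nbins <- max(deg) + 1L
  ref_hist <- tabulate(deg + 1L, nbins = nbins) / n

  l1 <- function(d_in, members) {
    sum(abs(tabulate(d_in[members] + 1L, nbins = nbins) / length(members) -
              ref_hist))
  }

  with_rng(config$rng_seed, {
    members <- sample.int(n, size)
    in_s <- logical(n)
    in_s[members] <- TRUE
    d_in <- integer(n)
    for (v in members) d_in[v] <- sum(in_s[adj[[v]]])
    delta <- l1(d_in, members)
    for (it in seq_len(config$n_iterations)) {
      if (size == n) break                       # nothing to swap
      u <- members[sample.int(size, 1L)]
      outside <- which(!in_s)
      w <- outside[sample.int(length(outside), 1L)]
      # trial update
      in_s[u] <- FALSE
      nb_u <- adj[[u]]
      d_in[nb_u] <- d_in[nb_u] - 1L
      in_s[w] <- TRUE
      nb_w <- adj[[w]]
      d_in[nb_w] <- d_in[nb_w] + 1L
      d_in[w] <- sum(in_s[nb_w])
      trial <- members
      trial[trial == u] <- w
      delta_new <- l1(d_in, trial)
      accept <- delta_new < delta ||
        (delta_new > 0 && runif(1L) <= delta / delta_new)
      if (accept) {
        members <- trial
        delta <- delta_new
      } else {                                   # revert
        in_s[w] <- FALSE
        d_in[nb_w] <- d_in[nb_w] - 1L
        in_s[u] <- TRUE
        d_in[nb_u] <- d_in[nb_u] + 1L
        d_in[u] <- sum(in_s[nb_u])
      }
    }
    el <- igraph::as_edgelist(graph, names = FALSE)
    storage.mode(el) <- "integer"
    keep <- in_s[el[, 1L]] & in_s[el[, 2L]]
    new_graph_sample("mh", graph, el[keep, , drop = FALSE], members, config,
                     0L)
  })
}

#' Subgraph induced by a sample
#'
#' Materializes a `graph_sample` as a graph: the edges are the crossed
#' edges and the nodes are the discovered nodes, so seeds that never
#' crossed an edge appear isolated. All sample-based centralities are
#' computed on this subgraph structure.
#'
#' @param sample A `graph_sample`.
#' @return An undirected simple igraph graph.
#' @export
sample_subgraph <- function(sample) {
  stopifnot(inherits(sample, "graph_sample"))
  graph_from_pairs(sample$crossed_edges, nodes = sample$discovered_nodes)
}

# Dispatch table used by run_experiment() and the command-line interface.
sampler_function <- function(algorithm) {
  switch(algorithm,
         maxrd = sample_max_rank_degree,
         ff = sample_forest_fire,
         mhrw = sample_mhrw,
         mh = sample_metropolis_hastings,
         stop("unknown sampling algorithm: ", algorithm, call. = FALSE))
}
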