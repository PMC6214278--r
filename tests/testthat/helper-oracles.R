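# Independent brute-force oracles used to validate the package's
# implementations on small fixtures. Each is written from the definition,
# not from the code path it checks.

# Core number by definition: max over all induced subgraphs containing v
# of the subgraph's minimum degree. Exponential; fixtures must stay small.
brute_force_core <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 12)
  el <- igraph::as_edgelist(g, names = FALSE)
  best <- integer(n)
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (!length(members)) next
    inside <- logical(n)
    inside[members] <- TRUE
    deg <- integer(n)
    if (nrow(el)) {
      keep <- inside[el[, 1L]] & inside[el[, 2L]]
      deg <- tabulate(c(el[keep, 1L], el[keep, 2L]), nbins = n)
    }
    mindeg <- min(deg[members])
    best[members] <- pmax(best[members], mindeg)
  }
  stats::setNames(best, igraph::V(g)$name)
}

# Betweenness by explicit shortest-path enumeration: for every unordered
# pair, list all simple paths, keep the shortest ones, and credit each
# interior vertex with its share.
brute_force_betweenness <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 12)
  bc <- stats::setNames(numeric(n), igraph::V(g)$name)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- suppressWarnings(
        igraph::all_simple_paths(g, from = s, to = t))
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      short <- paths[lens == min(lens)]
      for (p in short) {
        interior <- setdiff(as.integer(p), c(s, t))
        bc[interior] <- bc[interior] + 1 / length(short)
      }
    }
  }
  bc
}

# Exact mean SIR outbreak size per seed under gamma = 1 via the bond
# percolation mapping: each edge is independently occupied with
# probability beta; the outbreak from seed v is v's component in the
# occupied subgraph. Enumerates all 2^m edge subsets.
bond_percolation_mean <- function(g, beta) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  n <- igraph::vcount(g)
  stopifnot(m <= 16)
  mean_m <- numeric(n)
  for (code in seq_len(2^m) - 1L) {
    occ <- bitwAnd(code, 2^(seq_len(m) - 1L)) > 0
    p <- prod(ifelse(occ, beta, 1 - beta))
    sub <- igraph::make_empty_graph(n, directed = FALSE)
    if (any(occ)) sub <- igraph::add_edges(sub, t(el[occ, , drop = FALSE]))
    comp <- igraph::components(sub)
    mean_m <- mean_m + p * comp$csize[comp$membership]
  }
  stats::setNames(mean_m, igraph::V(g)$name)
}

# Kendall tau by exhaustive pair counting. x is a tie-free ordering
# (positions), y the scores the same elements carry in the reference
# ranking (higher = better). tau_b adjusts the denominator for ties in y.
brute_force_kendall <- function(y, variant = "tau_b") {
  k <- length(y)
  conc <- disc <- 0L
  ties_y <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      # element i precedes element j in the candidate ordering, so the
      # pair is concordant iff the reference also prefers i.
      if (y[i] > y[j]) conc <- conc + 1L
      else if (y[i] < y[j]) disc <- disc + 1L
      else ties_y <- ties_y + 1L
    }
  }
  n0 <- k * (k - 1L) / 2
  if (variant == "tau_a") return((conc - disc) / n0)
  if (n0 - ties_y == 0) return(NA_real_)
  (conc - disc) / sqrt(n0 * (n0 - ties_y))
}

# Discrete-time mean-field equilibrium density of synchronous SIS on the
# complete graph K_n: solves i = i(1-delta) + (1-i)(1-(1-nu)^(i(n-1)))
# by damped fixed-point iteration from a high start.
sis_meanfield_density <- function(n, nu, delta, iter = 10000) {
  i <- 0.9
  for (s in seq_len(iter)) {
    i_new <- i * (1 - delta) + (1 - i) * (1 - (1 - nu)^(i * (n - 1)))
    i <- 0.5 * i + 0.5 * i_new
  }
  i
}

# Small named test graphs used across files (all with character names).
toy_graphs <- function() {
  list(
    path4 = graph_from_pairs(cbind(c("a", "b", "c"), c("b", "c", "d"))),
    star5 = maxrd:::as_maxrd_graph(igraph::make_star(5, mode = "undirected")),
    triangle = maxrd:::as_maxrd_graph(igraph::make_full_graph(3)),
    k4_pendant = graph_from_pairs(cbind(c("1", "1", "1", "2", "2", "3", "4"),
                                        c("2", "3", "4", "3", "4", "4", "5"))),
    two_comp = make_fixture("union",
                            components = list(list(family = "complete", n = 4),
                                              list(family = "complete", n = 2)))$graph
  )
}
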