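#' Generate a fixture graph with analytically known properties
#'
#' Builds graphs from families whose degree moments, epidemic thresholds,
#' core numbers or component structure are known in closed form, so
#' every stage of the pipeline can be tested without external data. The
#' closed-form expectations are checked against the generated graph at
#' generation time; a mismatch is a hard error.
#'
#' Families and their expectations:
#' * `regular` (parameters `n`, `k`; `n * k` even): moments (k, k^2),
#'   SIR threshold 1/(k-1), SIS threshold 1/k, all core numbers k.
#' * `complete` (`n`): moments (n-1, (n-1)^2), all core numbers n-1.
#' * `star` (`n` nodes total): moments (2(n-1)/n, ((n-1)^2 + (n-1))/n),
#'   all core numbers 1 (for n >= 2).
#' * `path` (`n`): all core numbers 1.
#' * `erdos_renyi` (`n`, `p`): random G(n, p); only invariants are
#'   recorded (expected mean degree (n-1)p, not asserted).
#' * `barabasi_albert` (`n`, `m`): preferential attachment, m edges per
#'   new node; degree-heterogeneous, the default end-to-end fixture.
#'   Note that preferential attachment yields a constant core number
#'   (every node has core m), so its k-core carries no ranking signal.
#' * `power_law` (`n`, `m` = edge count, `exponent`): static power-law
#'   (fitness) graph; heavy-tailed with a non-degenerate k-core
#'   hierarchy whose innermost shells are small, as in real social
#'   networks — the fixture of choice when k-core must be informative.
#' * `union` (`components` = list of fixture argument lists): disjoint
#'   union with relabelled nodes; expected component sizes.
#'
#' @param family Fixture family name.
#' @param n Number of nodes.
#' @param k Degree of a regular graph.
#' @param m Edges per step for Barabasi-Albert.
#' @param p Edge probability for Erdos-Renyi.
#' @param exponent Degree-distribution exponent for `power_law`
#'   (`m` is the edge count there).
#' @param components For `family = "union"`: a list of argument lists,
#'   each passed on to `make_fixture()`.
#' @param rng_seed Seed for the random families.
#' @return An object of class `maxrd_fixture`: list with `graph` (an
#'   igraph object) and `expected` (named list of closed-form
#'   properties).
#' @examples
#' fx <- make_fixture("regular", n = 10, k = 4)
#' fx$expected$sir_threshold # 1/3
#' @export
make_fixture <- function(family = c("regular", "erdos_renyi",
                                    "barabasi_albert", "power_law", "star",
                                    "complete", "path", "union"),
                         n = NULL, k = NULL, m = NULL, p = NULL,
                         exponent = 2.0, components = NULL, rng_seed = 1L) {
  family <- match.arg(family)
  expected <- list(family = family)
  g <- switch(family,
    regular = {
      stopifnot(!is.null(n), !is.null(k), (n * k) %% 2 == 0, k < n)
      expected$degree_moments <- c(k, k^2)
      expected$sir_threshold <- if (k > 1) 1 / (k - 1) else NA_real_
      expected$sis_threshold <- 1 / k
      expected$core_numbers <- rep(k, n)
      with_rng(rng_seed, igraph::sample_k_regular(n, k))
    },
    complete = {
      stopifnot(!is.null(n), n >= 2)
      expected$degree_moments <- c(n - 1, (n - 1)^2)
      expected$core_numbers <- rep(n - 1, n)
      igraph::make_full_graph(n)
    },
    star = {
      stopifnot(!is.null(n), n >= 2)
      expected$degree_moments <- c(2 * (n - 1) / n,
                                   ((n - 1)^2 + (n - 1)) / n)
      expected$core_numbers <- rep(1, n)
      expected$center_betweenness <- choose(n - 1, 2)
      igraph::make_star(n, mode = "undirected")
    },
    path = {
      stopifnot(!is.null(n), n >= 2)
      expected$degree_moments <- c(2 * (n - 1) / n, (4 * (n - 2) + 2) / n)
      expected$core_numbers <- rep(1, n)
      igraph::make_lattice(n)
    },
    erdos_renyi = {
      stopifnot(!is.null(n), !is.null(p))
      expected$approx_mean_degree <- (n - 1) * p
      with_rng(rng_seed, igraph::sample_gnp(n, p))
    },
    barabasi_albert = {
      stopifnot(!is.null(n), !is.null(m))
      expected$approx_mean_degree <- 2 * m * (n - m) / n
      with_rng(rng_seed, igraph::sample_pa(n, m = m, directed = FALSE))
    },
    power_law = {
      stopifnot(!is.null(n), !is.null(m), exponent > 1)
      expected$approx_mean_degree <- 2 * m / n
      with_rng(rng_seed,
               igraph::sample_fitness_pl(n, m, exponent.out = exponent))
    },
    union = {
      stopifnot(is.list(components), length(components) >= 1)
      parts <- lapply(seq_along(components), function(i) {
        sub <- do.call(make_fixture,
                       c(components[[i]], list(rng_seed = mix_seed(rng_seed, i))))
        gg <- sub$graph
        igraph::V(gg)$name <- paste0("c", i, "_", igraph::V(gg)$name)
        gg
      })
      expected$component_sizes <- sort(vapply(parts,
                                              function(gg) as.integer(igraph::vcount(gg)),
                                              integer(1)))
      Reduce(igraph::disjoint_union, parts)
    })
  g <- as_maxrd_graph(g)
  verify_fixture(g, expected)
  structure(list(graph = g, expected = expected), class = "maxrd_fixture")
}

# Generation-time consistency check: the analytic expectations must hold
# exactly for the generated graph.
verify_fixture <- function(g, expected) {
  if (!is.null(expected$degree_moments)) {
    mom <- degree_moments(g)
    stopifnot(isTRUE(all.equal(mom$mean_degree, expected$degree_moments[1])),
              isTRUE(all.equal(mom$mean_squared_degree,
                               expected$degree_moments[2])))
  }
  if (!is.null(expected$core_numbers)) {
    stopifnot(identical(sort(as.integer(igraph::coreness(g))),
                        sort(as.integer(expected$core_numbers))))
  }
  if (!is.null(expected$component_sizes)) {
    stopifnot(identical(sort(as.integer(igraph::components(g)$csize)),
                        sort(as.integer(expected$component_sizes))))
  }
  invisible(TRUE)
}

#' @export
print.maxrd_fixture <- function(x, ...) {
  cat(sprintf("<maxrd_fixture> %s: %d nodes, %d edges\n",
              x$expected$family, igraph::vcount(x$graph),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Synthetic ground truth and candidate ranking pairs
#'
#' Builds a toy `ground_truth` with a controllable value profile plus a
#' candidate `ranked_list` whose top-k overlaps the ground-truth top-k
#' by exactly `overlap` nodes — handy for exercising the evaluation
#' statistics at known values (e.g. a requested OSim of `overlap / k`).
#'
#' @param n Number of nodes (>= 2).
#' @param profile `"linear"` (values n, n-1, ..., 1; tie-free) or
#'   `"uniform"` (all values equal).
#' @param k Top-k size of the constructed candidate.
#' @param overlap Number of ground-truth top-k nodes present in the
#'   candidate top-k (0..k; requires `n >= 2k - overlap`).
#' @param kind Ground-truth kind label; `"sir_efficiency"` values are
#'   the raw profile (in \[1, n\]), `"sis_persistence"` values are the
#'   profile rescaled to \[0, 1\].
#' @param rng_seed Seed for ranking tie-breaks.
#' @return A list with `ground_truth`, `candidate` and `k`.
#' @export
make_toy_ranking_fixture <- function(n, profile = c("linear", "uniform"),
                                     k = max(1L, round(0.1 * n)),
                                     overlap = k,
                                     kind = c("sir_efficiency",
                                              "sis_persistence"),
                                     rng_seed = 1L) {
  profile <- match.arg(profile)
  kind <- match.arg(kind)
  stopifnot(n >= 2, k >= 1, k <= n, overlap >= 0, overlap <= k,
            n >= 2 * k - overlap)
  nodes <- paste0("v", seq_len(n))
  vals <- if (profile == "linear") as.numeric(n:1) else rep(1, n)
  if (kind == "sis_persistence") vals <- vals / n
  values <- stats::setNames(vals, nodes)
  gt <- new_ground_truth(kind, values, config = NULL, n_simulations = 0L,
                         rng_seed = as.integer(rng_seed))
  gt_top <- top_k_nodes(gt$ranking, k)
  keep <- gt_top[seq_len(overlap)]
  outside <- setdiff(nodes, gt_top)
  filler <- outside[seq_len(k - overlap)]
  cand_top <- c(keep, filler)
  rest <- setdiff(nodes, cand_top)
  # candidate scores: strictly decreasing along its own ordering
  cand_scores <- stats::setNames(numeric(n), nodes)
  cand_scores[c(cand_top, rest)] <- as.numeric(n:1)
  candidate <- rank_nodes(cand_scores, rng_seed = rng_seed)
  list(ground_truth = gt, candidate = candidate, k = k)
}
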