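# Fixture with a unique strict residual-degree choice at every step when
# exploration starts at "a": the crossed-edge sequence below is
# hand-simulated from the selection rule (cross to the
# max-residual-degree neighbour, remove the crossed edge, repeat).
strict_trace_graph <- function() {
  graph_from_pairs(cbind(c("a", "b", "b", "c", "c", "c", "d"),
                         c("b", "c", "d", "d", "e", "f", "f")))
}

test_that("maxRD reproduces the hand-simulated trace on the strict fixture", {
  g <- strict_trace_graph()
  # traversal order a->b->c->d->f->c->e; rows carry the graph's own
  # edge orientation, so the f->c step appears as (c, f)
  expected <- rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                    c("d", "f"), c("c", "f"), c("c", "e"))
  for (seed in c(1L, 42L, 999L)) {   # no ties, no jumps: RNG is irrelevant
    s <- sample_max_rank_degree(
      g, sampler_config(target_fraction = 1, initial_seeds = "a",
                        rng_seed = seed))
    expect_identical(s$crossed_edges, expected)
    expect_equal(s$n_jumps, 0L)
  }
})

test_that("maxRD follows the residual-degree rule on a path", {
  g <- toy_graphs()$path4
  s <- sample_max_rank_degree(
    g, sampler_config(target_fraction = 0.75, initial_seeds = "a",
                      rng_seed = 1))
  # from a the only move is b; from b, c (residual degree 1) beats a (0)
  expect_identical(s$crossed_edges[1, ], c("a", "b"))
  expect_identical(s$crossed_edges[2, ], c("b", "c"))
})

test_that("maxRD on a star discovers the centre first", {
  g <- igraph::make_star(5, mode = "undirected")
  leaf <- igraph::V(g)$name[2]
  s <- sample_max_rank_degree(
    g, sampler_config(target_fraction = 0.4, initial_seeds = leaf,
                      rng_seed = 7))
  expect_true(all(c(leaf, igraph::V(g)$name[1]) %in% s$discovered_nodes))
})

sample_contract_ok <- function(s, g, target_fraction) {
  el <- igraph::as_edgelist(g)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  if (nrow(s$crossed_edges)) {
    skey <- paste(pmin(s$crossed_edges[, 1], s$crossed_edges[, 2]),
                  pmax(s$crossed_edges[, 1], s$crossed_edges[, 2]))
    expect_true(all(skey %in% ekey))            # crossed edges subset of E
    expect_false(any(duplicated(skey)))         # no edge crossed twice
    expect_true(all(c(s$crossed_edges) %in% s$discovered_nodes))
  }
  expect_gte(length(s$discovered_nodes),
             ceiling(target_fraction * igraph::vcount(g)))
  expect_true(all(s$discovered_nodes %in% igraph::V(g)$name))
}

test_that("all four samplers honour the sample contracts on fixtures", {
  fixtures <- list(make_fixture("barabasi_albert", n = 120, m = 3,
                                rng_seed = 5)$graph,
                   make_fixture("erdos_renyi", n = 80, p = 0.08,
                                rng_seed = 9)$graph,
                   make_fixture("regular", n = 60, k = 4,
                                rng_seed = 3)$graph)
  for (g in fixtures) {
    for (alg in c("maxrd", "ff", "mhrw", "mh")) {
      for (seed in c(1L, 17L)) {
        cfg <- sampler_config(target_fraction = 0.25, rng_seed = seed,
                              n_iterations = 300)
        s <- maxrd:::sampler_function(alg)(g, cfg)
        sample_contract_ok(s, g, 0.25)
      }
    }
  }
})

test_that("fixed-seed maxRD runs are bit-identical", {
  g <- make_fixture("barabasi_albert", n = 150, m = 2, rng_seed = 11)$graph
  cfg <- sampler_config(target_fraction = 0.3, rng_seed = 23)
  s1 <- sample_max_rank_degree(g, cfg)
  s2 <- sample_max_rank_degree(g, cfg)
  expect_identical(s1$crossed_edges, s2$crossed_edges)
  expect_identical(s1$discovered_nodes, s2$discovered_nodes)
})

test_that("immediate-halt contract: target covered by the seeds themselves", {
  g <- toy_graphs()$two_comp
  cfg <- sampler_config(target_fraction = 2 / igraph::vcount(g),
                        seed_count = 2, rng_seed = 4)
  s <- sample_max_rank_degree(g, cfg)
  expect_gte(length(s$discovered_nodes), 2)
})

test_that("forest fire geometric draw has mean p_f / (1 - p_f)", {
  withr::with_seed(101, {
    draws <- rgeom(1e5, prob = 1 - 0.7)
    expect_equal(mean(draws), 0.7 / 0.3, tolerance = 0.02)
  })
})

test_that("forest fire burns everything at target fraction 1", {
  g <- toy_graphs()$triangle
  s <- sample_forest_fire(g, sampler_config(target_fraction = 1,
                                            seed_count = 1, rng_seed = 2))
  expect_setequal(s$discovered_nodes, igraph::V(g)$name)
})

test_that("MHRW long-run visit distribution is uniform on a non-regular graph", {
  g <- toy_graphs()$k4_pendant           # K4 plus a pendant: degrees 3,3,3,4,1
  adj <- maxrd:::adjacency_index(g)
  deg <- igraph::degree(g)
  n_steps <- 1e5
  visits <- withr::with_seed(31, {
    counts <- integer(igraph::vcount(g))
    x <- 1L
    for (i in seq_len(n_steps)) {
      x <- maxrd:::mhrw_step(adj, deg, x)
      counts[x] <- counts[x] + 1L
    }
    counts
  })
  p <- suppressWarnings(stats::chisq.test(visits)$p.value)
  expect_gt(p, 1e-3)
})

test_that("MHRW acceptance is certain on regular graphs and towards lower degree", {
  # on a regular graph deg(x)/deg(y) = 1, so the walk never rejects:
  # every round moves every walker
  g <- make_fixture("regular", n = 30, k = 4, rng_seed = 2)$graph
  s <- sample_mhrw(g, sampler_config(target_fraction = 0.5, seed_count = 1,
                                     rng_seed = 8))
  expect_gte(length(s$discovered_nodes), 15)
  # from the star centre any leaf proposal has deg ratio 4/1 >= 1: accept
  star <- igraph::make_star(5, mode = "undirected")
  adj <- maxrd:::adjacency_index(star)
  deg <- igraph::degree(star)
  withr::with_seed(5, {
    moved <- replicate(50, maxrd:::mhrw_step(adj, deg, 1L))
    expect_true(all(moved != 1L))
  })
})

test_that("MH sampler improves or keeps its histogram distance and returns an induced subgraph", {
  g <- make_fixture("barabasi_albert", n = 80, m = 2, rng_seed = 13)$graph
  cfg <- sampler_config(target_fraction = 0.25, rng_seed = 3,
                        n_iterations = 400)
  s <- sample_metropolis_hastings(g, cfg)
  # crossed edges are exactly the induced edges on the discovered nodes
  sub_direct <- igraph::induced_subgraph(g, s$discovered_nodes)
  expect_equal(nrow(s$crossed_edges), igraph::ecount(sub_direct))
  # the whole graph as sample has distance zero and stays put
  cfg_full <- sampler_config(target_fraction = 1, rng_seed = 3,
                             n_iterations = 50)
  s_full <- sample_metropolis_hastings(g, cfg_full)
  expect_setequal(s_full$discovered_nodes, igraph::V(g)$name)
})

test_that("sample_subgraph keeps isolated seeds and stays inside the graph", {
  g <- toy_graphs()$two_comp
  s <- sample_max_rank_degree(
    g, sampler_config(target_fraction = 0.5, seed_count = 1, rng_seed = 6))
  sub <- sample_subgraph(s)
  expect_setequal(igraph::V(sub)$name, s$discovered_nodes)
  fake <- structure(list(algorithm = "maxrd",
                         crossed_edges = matrix(character(0), ncol = 2),
                         discovered_nodes = "c1_1",
                         config = NULL, rng_seed = 1L, n_jumps = 0L),
                    class = "graph_sample")
  sub2 <- sample_subgraph(fake)
  expect_equal(igraph::vcount(sub2), 1)
  expect_equal(igraph::ecount(sub2), 0)
})
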