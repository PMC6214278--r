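test_that("threshold formulas match closed forms and guard their domain", {
  expect_equal(sir_threshold(c(4, 16)), 1 / 3)      # 4-regular
  expect_equal(sir_threshold(c(5, 25)), 0.25)       # 5-regular: 1/(k-1)
  expect_equal(sir_threshold(c(1.6, 4.0)), 1.6 / 2.4)  # 5-node star
  expect_equal(sis_threshold(c(4, 16)), 0.25)       # k-regular: 1/k
  # a perfect matching (1-regular) has <k^2> = <k>: SIR threshold undefined
  expect_error(sir_threshold(c(1, 1)), "undefined")
  expect_error(sis_threshold(c(0, 0)), "undefined")
  fx <- make_fixture("regular", n = 10, k = 4)
  expect_equal(sir_threshold(degree_moments(fx$graph)),
               fx$expected$sir_threshold)
  expect_equal(sis_threshold(degree_moments(fx$graph)),
               fx$expected$sis_threshold)
})

test_that("SIR with beta = 0 infects nobody beyond the seed", {
  g <- toy_graphs()$k4_pendant
  for (v in igraph::V(g)$name) {
    expect_equal(simulate_sir(g, sir_config(beta = 0, rng_seed = 3), v), 1L)
  }
})

test_that("SIR with beta = 1, gamma = 1 sweeps the seed's component exactly", {
  fixtures <- list(toy_graphs()$two_comp, toy_graphs()$path4,
                   make_fixture("erdos_renyi", n = 30, p = 0.05,
                                rng_seed = 14)$graph)
  for (g in fixtures) {
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    for (vi in seq_len(igraph::vcount(g))) {
      v <- igraph::V(g)$name[vi]
      expect_equal(simulate_sir(g, sir_config(beta = 1, rng_seed = vi), v),
                   unname(sizes[vi]))
    }
  }
})

test_that("SIR mean outbreak matches bond-percolation enumeration", {
  # reduced-replication version of the full acceptance check
  g <- toy_graphs()$k4_pendant
  beta <- 0.5
  oracle <- bond_percolation_mean(g, beta)
  adj <- maxrd:::adjacency_index(g)
  n_rep <- 4000
  for (vi in c(1L, 5L)) {
    sizes <- vapply(seq_len(n_rep), function(r) {
      maxrd:::with_rng(maxrd:::mix_seed(99, vi, r),
                       maxrd:::sir_run(adj, vi, beta, 1))
    }, numeric(1))
    se <- stats::sd(sizes) / sqrt(n_rep)
    expect_lt(abs(mean(sizes) - oracle[vi]), 3 * se + 1e-9)
  }
})

test_that("SIR mean outbreak size is monotone in beta", {
  g <- make_fixture("barabasi_albert", n = 60, m = 2, rng_seed = 4)$graph
  adj <- maxrd:::adjacency_index(g)
  means <- vapply(c(0.05, 0.2, 0.5, 1), function(beta) {
    mean(vapply(1:300, function(r) {
      maxrd:::with_rng(maxrd:::mix_seed(7, r),
                       maxrd:::sir_run(adj, 1L, beta, 1))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("SIR ground truth averages per-node efficiencies", {
  g <- toy_graphs()$two_comp
  gt <- sir_ground_truth(g, sir_config(beta = 1, n_simulations = 3,
                                       rng_seed = 2))
  expect_equal(unname(gt$values[startsWith(names(gt$values), "c1")]),
               rep(4, 4))
  expect_equal(unname(gt$values[startsWith(names(gt$values), "c2")]),
               rep(2, 2))
  gt0 <- sir_ground_truth(g, sir_config(beta = 0, n_simulations = 2,
                                        rng_seed = 2))
  expect_true(all(gt0$values == 1))
  expect_setequal(gt0$ranking$ordered_nodes, names(gt0$values))
})

test_that("ground-truth values stabilise as simulations grow", {
  g <- make_fixture("erdos_renyi", n = 40, p = 0.1, rng_seed = 6)$graph
  cfg <- function(ns, seed) sir_config(beta = 0.3, n_simulations = ns,
                                       rng_seed = seed)
  spread <- function(ns) {
    a <- sir_ground_truth(g, cfg(ns, 1))$values
    b <- sir_ground_truth(g, cfg(ns, 2))$values
    mean(abs(a - b))
  }
  expect_lt(spread(60), spread(5))
})

test_that("SIR calibration returns the first passing grid point", {
  g <- make_fixture("barabasi_albert", n = 100, m = 3, rng_seed = 10)$graph
  base <- sir_config(beta = 0, n_simulations = 10, rng_seed = 5)
  cal <- calibrate_sir(g, base, p_grid = seq(1, 3, by = 0.5))
  expect_true(cal$p %in% seq(1, 3, by = 0.5))
  expect_equal(cal$t_star, cal$p * cal$t_c)
  # reproducible under the same seed
  cal2 <- calibrate_sir(g, base, p_grid = seq(1, 3, by = 0.5))
  expect_identical(cal, cal2)
  # a stricter efficiency bar can only push the calibrated p up
  cal_hi <- calibrate_sir(g, base, p_grid = seq(1, 6, by = 0.5),
                          efficiency_fraction = 0.05)
  expect_gte(cal_hi$p, cal$p)
  # an impossible criterion errors out reporting the last p tried
  expect_error(calibrate_sir(g, base, p_grid = c(1),
                             efficiency_fraction = 2),
               "last p tried: 1")
})

test_that("equilibrium detection follows the rest-then-window protocol", {
  pol <- equilibrium_policy(rest_periods = 5, window_periods = 4,
                            tolerance = 0)
  # constant trajectory: first non-negative increment at period 2,
  # declaration exactly rest + window periods later
  res <- detect_equilibrium(rep(50, 30), pol)
  expect_true(res$reached)
  expect_equal(res$period, 2 + 5 + 4)
  # strictly decreasing: never
  res <- detect_equilibrium(seq(100, 10, by = -1), pol)
  expect_false(res$reached)
  # sawtooth around a constant: window increments are -1,+1,... summing
  # to zero over an even window (hand-checked with rest = 3, window = 4:
  # first increment >= 0 is the second one, window covers increments
  # 6..9, declaration at period 10)
  pol2 <- equilibrium_policy(rest_periods = 3, window_periods = 4,
                             tolerance = 0)
  saw <- rep(c(10, 9), 10)
  res <- detect_equilibrium(saw, pol2)
  expect_true(res$reached)
  expect_equal(res$period, 10)
})

test_that("SIS dies out without infection and saturates without recovery", {
  g <- igraph::make_full_graph(12)
  eq <- equilibrium_policy(rest_periods = 5, window_periods = 5,
                           max_periods = 500)
  run <- simulate_sis(g, sis_config(nu = 0, delta = 0.8, rng_seed = 3,
                                    equilibrium = eq))
  expect_true(run$extinct)
  expect_true(all(run$persistence == 0))
  run <- simulate_sis(g, sis_config(nu = 0.6, delta = 0.01, rng_seed = 3,
                                    equilibrium = eq))
  expect_false(run$extinct)
  expect_gt(run$equilibrium_density, 0.9)
})

test_that("SIS equilibrium density on K_n matches the discrete mean-field fixed point", {
  n <- 20; nu <- 0.3; delta <- 0.8
  oracle <- sis_meanfield_density(n, nu, delta)
  eq <- equilibrium_policy(rest_periods = 50, window_periods = 50,
                           max_periods = 5000)
  dens <- vapply(1:8, function(r) {
    simulate_sis(igraph::make_full_graph(n),
                 sis_config(nu = nu, delta = delta, rng_seed = r,
                            measure_periods = 200,
                            equilibrium = eq))$equilibrium_density
  }, numeric(1))
  expect_equal(mean(dens), oracle, tolerance = 0.08)
})

test_that("SIS persistence is invariant under node relabelling", {
  g <- make_fixture("barabasi_albert", n = 40, m = 2, rng_seed = 9)$graph
  perm <- withr::with_seed(2, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  eq <- equilibrium_policy(rest_periods = 20, window_periods = 20,
                           max_periods = 2000)
  cfg <- sis_config(nu = 0.4, delta = 0.8, n_simulations = 30,
                    measure_periods = 50, equilibrium = eq, rng_seed = 7)
  v1 <- sis_ground_truth(g, cfg)$values
  v2 <- sis_ground_truth(g2, cfg)$values
  # same node names, same graph up to relabelling: averaged persistence
  # must agree within Monte-Carlo error
  expect_equal(sort(names(v1)), sort(names(v2)))
  expect_equal(unname(v1[names(v1)]), unname(v2[names(v1)]),
               tolerance = 0.12)
})

test_that("SIS calibration orders lambda_hat <= lambda_star and errors when impossible", {
  g <- igraph::make_full_graph(30)
  eq <- equilibrium_policy(rest_periods = 10, window_periods = 10,
                           max_periods = 1000)
  base <- sis_config(nu = 0.1, delta = 0.8, rng_seed = 4,
                     measure_periods = 30, equilibrium = eq)
  cal <- calibrate_sis(g, base, p_grid = seq(1, 3, by = 0.5),
                       n_replicates = 3)
  expect_lte(cal$lambda_hat, cal$lambda_star)
  expect_true(cal$p_hat %in% seq(1, 3, by = 0.5))
  expect_equal(cal$lambda_c, sis_threshold(degree_moments(g)))
  # a grid whose single point is far above threshold passes both scans
  # at that point: lambda_hat = lambda_star
  cal8 <- calibrate_sis(g, base, p_grid = c(8), n_replicates = 3)
  expect_equal(cal8$lambda_hat, cal8$lambda_star)
  expect_equal(cal8$lambda_star, 8 * cal8$lambda_c)
  expect_error(calibrate_sis(g, base, p_grid = c(1), n_replicates = 2,
                             density_fraction = 2),
               "grid exhausted")
})

test_that("SIS ground truth ranks dense-component nodes above sparse ones", {
  fx <- make_fixture("union",
                     components = list(list(family = "complete", n = 8),
                                       list(family = "path", n = 6)))
  eq <- equilibrium_policy(rest_periods = 10, window_periods = 10,
                           max_periods = 1000)
  cfg <- sis_config(nu = 0.25, delta = 0.8, n_simulations = 20,
                    measure_periods = 50, equilibrium = eq, rng_seed = 11)
  gt <- sis_ground_truth(fx$graph, cfg)
  expect_true(all(gt$values >= 0 & gt$values <= 1))
  dense <- mean(gt$values[startsWith(names(gt$values), "c1")])
  sparse <- mean(gt$values[startsWith(names(gt$values), "c2")])
  expect_gt(dense, sparse)
})
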