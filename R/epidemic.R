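#' Theoretical epidemic thresholds from degree moments
#'
#' For heterogeneous networks the critical points of the two epidemic
#' models are determined by the first two moments of the degree
#' distribution: the SIR control parameter T = beta/gamma has threshold
#' `<k> / (<k^2> - <k>)`, and the SIS effective spreading rate
#' lambda = nu/delta has threshold `<k> / <k^2>`. Above the threshold an
#' epidemic outbreak (SIR) or a stable endemic phase (SIS) occurs.
#'
#' @param moments A `degree_moments` object (see [degree_moments()]), a
#'   numeric pair `c(mean_degree, mean_squared_degree)`, or a graph.
#' @return The threshold value, a single number.
#' @examples
#' sir_threshold(c(43.69, 4656.14)) # ~0.0095
#' sis_threshold(c(43.69, 4656.14)) # ~0.0094
#' @name epidemic_thresholds
NULL

#' @rdname epidemic_thresholds
#' @export
sir_threshold <- function(moments) {
  m <- as_degree_moments(moments)
  if (m$mean_squared_degree <= m$mean_degree) {
    stop("SIR threshold undefined: <k^2> must exceed <k>", call. = FALSE)
  }
  m$mean_degree / (m$mean_squared_degree - m$mean_degree)
}

#' @rdname epidemic_thresholds
#' @export
sis_threshold <- function(moments) {
  m <- as_degree_moments(moments)
  if (m$mean_squared_degree <= 0) {
    stop("SIS threshold undefined: <k^2> must be positive", call. = FALSE)
  }
  m$mean_degree / m$mean_squared_degree
}

#' SIR simulation configuration
#'
#' @param beta Per-period infection probability along each
#'   infected-susceptible edge, in \[0, 1\].
#' @param gamma Per-period recovery probability, in (0, 1\]; the
#'   reference experiments fix gamma = 1, making each node infectious for
#'   exactly one period. The control parameter T = beta/gamma is always
#'   derived, never stored.
#' @param n_simulations Number of independent simulation instances over
#'   which node efficiencies are averaged (reference setup: 1000).
#' @param rng_seed Integer master seed; per-trial streams are derived
#'   from (rng_seed, instance, seed node) so the |N|-trial sweep is
#'   reproducible.
#' @return An object of class `sir_config`.
#' @export
sir_config <- function(beta, gamma = 1, n_simulations = 1000L, rng_seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, gamma > 0, gamma <= 1, n_simulations >= 1)
  structure(list(beta = beta, gamma = gamma,
                 n_simulations = as.integer(n_simulations),
                 rng_seed = as.integer(rng_seed)),
            class = "sir_config")
}

# Core discrete-time SIR run on an integer adjacency list. Synchronous
# periods: every infected node first tries to infect each susceptible
# neighbour (prob beta per contact), then recovers (prob gamma); newly
# infected nodes neither transmit nor recover until the next period.
# Returns the number of ever-infected nodes, counting the seed.
sir_run <- function(adj, seed_idx, beta, gamma) {
  ever <- seed_idx
  infected <- seed_idx
  n_ever <- 1L
  ever_flag <- rep(FALSE, length(adj))
  ever_flag[seed_idx] <- TRUE
  while (length(infected)) {
    targets <- unlist(adj[infected], use.names = FALSE)
    new <- integer(0)
    if (length(targets) && beta > 0) {
      hit <- targets[runif(length(targets)) < beta]
      hit <- hit[!ever_flag[hit]]
      if (length(hit)) {
        new <- unique(hit)
        ever_flag[new] <- TRUE
        n_ever <- n_ever + length(new)
      }
    }
    infected <- if (gamma >= 1) {
      new
    } else {
      c(infected[runif(length(infected)) >= gamma], new)
    }
  }
  n_ever
}

#' Simulate one SIR epidemic from a seed node
#'
#' Discrete-time synchronous SIR dynamics started from a single infected
#' node, run to extinction. Returns the outbreak size M: the number of
#' nodes that were ever infected, including the seed, so M is in
#' \[1, |N|\]. With beta = 1 and gamma = 1 the epidemic sweeps the seed's
#' entire connected component.
#'
#' @param graph An undirected igraph graph.
#' @param config An [sir_config()].
#' @param seed_node Name of the initially infected node.
#' @return Integer outbreak size.
#' @export
simulate_sir <- function(graph, config, seed_node) {
  graph <- as_maxrd_graph(graph)
  idx <- match(as.character(seed_node), igraph::V(graph)$name)
  if (is.na(idx)) stop("seed node not in graph: ", seed_node, call. = FALSE)
  adj <- adjacency_index(graph)
  with_rng(config$rng_seed, sir_run(adj, idx, config$beta, config$gamma))
}

# Instance-by-node matrix of outbreak sizes: each of n_instances rows is
# one simulation instance of |N| trials, one SIR run per seed node, each
# trial on its own derived RNG stream.
sir_efficiency_matrix <- function(adj, beta, gamma, n_instances, rng_seed) {
  n <- length(adj)
  M <- matrix(0L, nrow = n_instances, ncol = n)
  for (i in seq_len(n_instances)) {
    for (v in seq_len(n)) {
      M[i, v] <- with_rng(mix_seed(rng_seed, i, v),
                          sir_run(adj, v, beta, gamma))
    }
  }
  M
}

new_ground_truth <- function(kind, values, config, n_simulations, rng_seed) {
  structure(list(kind = kind,
                 values = values,
                 ranking = rank_nodes(values, rng_seed = rng_seed),
                 config = config,
                 n_simulations = n_simulations,
                 rng_seed = rng_seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s over %d nodes (%d simulations, rng_seed %d)\n",
              x$kind, length(x$values), x$n_simulations, x$rng_seed))
  invisible(x)
}

#' SIR ground truth: mean spreading efficiency per node
#'
#' Runs `n_simulations` independent simulation instances; each instance
#' consists of |N| trials, one [simulate_sir()] run per node taken as the
#' epidemic seed. A node's spreading efficiency is its mean outbreak size
#' M across instances, and the ground-truth ranking orders nodes by these
#' values (ties broken by seeded shuffle).
#'
#' @param graph An undirected igraph graph.
#' @param config An [sir_config()].
#' @return An object of class `ground_truth` with `kind`
#'   `"sir_efficiency"`, the per-node `values` and their `ranking`.
#' @export
sir_ground_truth <- function(graph, config) {
  graph <- as_maxrd_graph(graph)
  adj <- adjacency_index(graph)
  M <- sir_efficiency_matrix(adj, config$beta, config$gamma,
                             config$n_simulations, config$rng_seed)
  values <- stats::setNames(colMeans(M), igraph::V(graph)$name)
  new_ground_truth("sir_efficiency", values, config, config$n_simulations,
                   config$rng_seed)
}

#' Calibrate the SIR control parameter
#'
#' Scans T = p x T^c over an ascending grid of p values (default 1, 1.1,
#' 1.2, ...). For each p the full ground-truth procedure is run and the
#' calibration criterion checked: in every simulation instance, the
#' top-20 percent most efficient nodes of that instance must have mean
#' epidemic efficiency strictly larger than 1 percent of the graph size.
#' The scan returns the first passing value T* = p x T^c; the epidemic is
#' then just above the effective threshold of the network, where the
#' ground-truth ranking is most discriminative.
#'
#' @param graph An undirected igraph graph.
#' @param base An [sir_config()]; its `beta` is ignored, its `gamma`,
#'   `n_simulations` and `rng_seed` are used for the scan.
#' @param p_grid Increasing multipliers of the theoretical threshold.
#' @param top_fraction,efficiency_fraction The criterion's two knobs:
#'   the fraction of top nodes examined (0.20) and the outbreak-size bar
#'   as a fraction of |N| (0.01).
#' @return A list with `p`, `t_star` (= p x T^c), `beta` (= T* x gamma)
#'   and `t_c`.
#' @export
calibrate_sir <- function(graph, base, p_grid = seq(1, 3, by = 0.1),
                          top_fraction = 0.20, efficiency_fraction = 0.01) {
  stopifnot(length(p_grid) >= 1)
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  adj <- adjacency_index(graph)
  t_c <- sir_threshold(degree_moments(graph))
  k20 <- max(1L, as.integer(round(top_fraction * n)))
  bar <- efficiency_fraction * n
  for (p in p_grid) {
    beta <- min(1, p * t_c * base$gamma)
    M <- sir_efficiency_matrix(adj, beta, base$gamma, base$n_simulations,
                               mix_seed(base$rng_seed, round(p * 1000)))
    top_means <- apply(M, 1L, function(row) {
      mean(sort(row, decreasing = TRUE)[seq_len(k20)])
    })
    if (all(top_means > bar)) {
      return(list(p = p, t_star = p * t_c, beta = beta, t_c = t_c))
    }
  }
  stop("SIR calibration: no grid value passed the efficiency criterion ",
       "(last p tried: ", p_grid[length(p_grid)], ")", call. = FALSE)
}

#' Equilibrium-detection policy for SIS dynamics
#'
#' The endemic equilibrium is detected from the trajectory of the number
#' of infected nodes I(t) via its increments Delta(I) = I(t+1) - I(t).
#' Early in a run Delta(I) is negative; once Delta(I) >= 0 is first
#' observed the system is left to rest for `rest_periods` periods, after
#' which increments are accumulated. Equilibrium is declared at the first
#' period with at least `window_periods` accumulated increments whose
#' mean is within `tolerance` of zero (the overall gain or loss over the
#' window must be close to zero).
#'
#' @param rest_periods Rest length after the first non-negative
#'   increment (reference protocol: 100).
#' @param window_periods Minimum number of accumulated increments
#'   (reference protocol: 100 or more).
#' @param tolerance Bound on |mean Delta(I)| in infected nodes per
#'   period; default 0.5.
#' @param max_periods Safety cap on the total simulated periods.
#' @return An object of class `equilibrium_policy`.
#' @export
equilibrium_policy <- function(rest_periods = 100L, window_periods = 100L,
                               tolerance = 0.5, max_periods = 100000L) {
  stopifnot(rest_periods >= 1, window_periods >= 1, tolerance >= 0,
            max_periods >= 1)
  structure(list(rest_periods = as.integer(rest_periods),
                 window_periods = as.integer(window_periods),
                 tolerance = tolerance,
                 max_periods = as.integer(max_periods)),
            class = "equilibrium_policy")
}

#' Detect the endemic equilibrium in an infection trajectory
#'
#' Offline version of the equilibrium protocol described in
#' [equilibrium_policy()], applied to a recorded trajectory of infected
#' counts. With first non-negative increment at period t0, the earliest
#' possible declaration is period t0 + rest_periods + window_periods.
#'
#' @param trajectory Numeric vector, I(t) per period (any consistent
#'   unit; `policy$tolerance` is interpreted in the same unit).
#' @param policy An [equilibrium_policy()].
#' @return A list with `reached` (logical), `start_period` (first period
#'   whose increment enters the averaging window) and `period` (the
#'   period at which equilibrium was declared; NA if never).
#' @export
detect_equilibrium <- function(trajectory, policy = equilibrium_policy()) {
  stopifnot(inherits(policy, "equilibrium_policy"))
  T_ <- length(trajectory)
  if (T_ < 2L) {
    return(list(reached = FALSE, start_period = NA_integer_,
                period = NA_integer_))
  }
  d <- diff(trajectory)                 # d[t] = I(t+1) - I(t), t = 1..T-1
  t0 <- which(d >= 0)[1L]               # first non-negative increment
  if (is.na(t0)) {
    return(list(reached = FALSE, start_period = NA_integer_,
                period = NA_integer_))
  }
  start <- t0 + policy$rest_periods + 1L  # first increment index accumulated
  csum <- 0
  count <- 0L
  t <- start
  while (t <= T_ - 1L) {
    csum <- csum + d[t]
    count <- count + 1L
    if (count >= policy$window_periods && abs(csum / count) <= policy$tolerance) {
      return(list(reached = TRUE, start_period = start, period = t + 1L))
    }
    t <- t + 1L
  }
  list(reached = FALSE, start_period = start, period = NA_integer_)
}

#' SIS simulation configuration
#'
#' @param nu Per-period infection probability along each
#'   infected-susceptible edge, in \[0, 1\].
#' @param delta Per-period recovery probability, in (0, 1\]; the
#'   reference experiments fix delta = 0.8. The effective spreading rate
#'   lambda = nu/delta is always derived.
#' @param initial_infected_fraction Fraction of nodes infected at t = 0
#'   (reference setup: 0.20).
#' @param n_simulations Number of independent runs over which node
#'   persistence is averaged by [sis_ground_truth()].
#' @param measure_periods Length of the persistence measurement window
#'   after equilibrium is declared.
#' @param equilibrium An [equilibrium_policy()].
#' @param rng_seed Integer master seed.
#' @return An object of class `sis_config`.
#' @export
sis_config <- function(nu, delta = 0.8, initial_infected_fraction = 0.2,
                       n_simulations = 1000L, measure_periods = 100L,
                       equilibrium = equilibrium_policy(), rng_seed = 1L) {
  stopifnot(nu >= 0, nu <= 1, delta > 0, delta <= 1,
            initial_infected_fraction > 0, initial_infected_fraction < 1,
            n_simulations >= 1, measure_periods >= 1,
            inherits(equilibrium, "equilibrium_policy"))
  structure(list(nu = nu, delta = delta,
                 initial_infected_fraction = initial_infected_fraction,
                 n_simulations = as.integer(n_simulations),
                 measure_periods = as.integer(measure_periods),
                 equilibrium = equilibrium,
                 rng_seed = as.integer(rng_seed)),
            class = "sis_config")
}

# One synchronous SIS period: infections from the old infected set (prob
# nu per infected-susceptible contact), then recoveries among the old
# infected (prob delta); a node infected this period cannot recover this
# period. `state` is a logical vector. Returns the new state.
sis_period <- function(adj, state, nu, delta) {
  inf <- which(state)
  new <- integer(0)
  if (length(inf) && nu > 0) {
    targets <- unlist(adj[inf], use.names = FALSE)
    if (length(targets)) {
      hit <- targets[runif(length(targets)) < nu]
      new <- unique(hit[!state[hit]])
    }
  }
  if (length(inf) && delta > 0) {
    rec <- inf[runif(length(inf)) < delta]
    state[rec] <- FALSE
  }
  state[new] <- TRUE
  state
}

#' Simulate one SIS epidemic to its endemic equilibrium
#'
#' Starts with a uniform random 20 percent (configurable) of nodes
#' infected and iterates synchronous periods: infections with
#' probability `nu` per infected-susceptible edge, then recoveries with
#' probability `delta` among previously infected nodes. The run tracks
#' the infected count I(t) and applies the equilibrium protocol of
#' [equilibrium_policy()] online; once equilibrium is declared, node
#' persistence rho_v is measured as the fraction of the following
#' `measure_periods` periods in which v is infected.
#'
#' If the infection dies out before equilibrium the run returns all-zero
#' persistence with `extinct = TRUE` — below the effective threshold
#' this is the expected long-run outcome, not an error. Exceeding
#' `max_periods` without equilibrium is an error ("no equilibrium").
#'
#' @param graph An undirected igraph graph.
#' @param config An [sis_config()].
#' @return A list with `persistence` (named numeric in \[0, 1\]),
#'   `trajectory` (density of infected nodes per period, including the
#'   measurement window), `equilibrium` (as [detect_equilibrium()]),
#'   `extinct`, and `equilibrium_density` (mean density over the
#'   measurement window; 0 if extinct).
#' @export
simulate_sis <- function(graph, config) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot simulate on an empty graph", call. = FALSE)
  adj <- adjacency_index(graph)
  pol <- config$equilibrium
  with_rng(config$rng_seed, {
    state <- logical(n)
    state[sample.int(n, max(1L, ceiling(config$initial_infected_fraction * n)))] <- TRUE
    traj <- sum(state)
    # online equilibrium tracking
    seen_nonneg <- FALSE
    rest_left <- pol$rest_periods
    csum <- 0
    count <- 0L
    reached <- FALSE
    extinct <- FALSE
    t <- 1L
    while (!reached) {
      if (t >= pol$max_periods) {
        stop("SIS: no equilibrium within max_periods = ", pol$max_periods,
             call. = FALSE)
      }
      prev <- traj[t]
      state <- sis_period(adj, state, config$nu, config$delta)
      t <- t + 1L
      traj[t] <- sum(state)
      if (traj[t] == 0L) { extinct <- TRUE; break }
      dI <- traj[t] - prev
      if (!seen_nonneg) {
        if (dI >= 0) seen_nonneg <- TRUE
      } else if (rest_left > 0L) {
        rest_left <- rest_left - 1L
      } else {
        csum <- csum + dI
        count <- count + 1L
        if (count >= pol$window_periods &&
            abs(csum / count) <= pol$tolerance) {
          reached <- TRUE
        }
      }
    }
    persistence <- stats::setNames(numeric(n), igraph::V(graph)$name)
    eq_density <- 0
    if (reached) {
      freq <- integer(n)
      for (s in seq_len(config$measure_periods)) {
        state <- sis_period(adj, state, config$nu, config$delta)
        t <- t + 1L
        traj[t] <- sum(state)
        freq <- freq + state
      }
      persistence[] <- freq / config$measure_periods
      eq_density <- mean(utils::tail(traj, config$measure_periods)) / n
    }
    list(persistence = persistence,
         trajectory = traj / n,
         equilibrium = list(reached = reached,
                            period = if (reached) t - config$measure_periods
                                     else NA_integer_),
         extinct = extinct,
         equilibrium_density = eq_density)
  })
}

#' Calibrate the SIS effective spreading rate
#'
#' Scans lambda = p x lambda^c over an ascending grid. Two rates are
#' estimated: `lambda_hat`, the smallest grid value for which the
#' density of infected nodes is non-zero in the long run (a stable
#' endemic equilibrium is reached rather than extinction), and
#' `lambda_star >= lambda_hat`, the smallest grid value whose average
#' equilibrium density is at least 1 percent of the graph. Each grid
#' point is judged over `n_replicates` independent runs: the epidemic
#' phase requires a majority of runs to reach a non-zero equilibrium,
#' and the equilibrium density is averaged over all runs (extinct runs
#' contribute zero).
#'
#' @param graph An undirected igraph graph.
#' @param base An [sis_config()]; its `nu` is ignored, its `delta` and
#'   protocol settings are used.
#' @param p_grid Increasing multipliers of the theoretical threshold.
#' @param n_replicates Runs per grid point.
#' @param density_fraction The equilibrium-density bar (0.01).
#' @return A list with `lambda_hat`, `lambda_star`, the corresponding
#'   grid multipliers `p_hat` and `p_star`, and `lambda_c`.
#' @export
calibrate_sis <- function(graph, base, p_grid = seq(1, 3, by = 0.1),
                          n_replicates = 5L, density_fraction = 0.01) {
  stopifnot(length(p_grid) >= 1)
  graph <- as_maxrd_graph(graph)
  lambda_c <- sis_threshold(degree_moments(graph))
  p_hat <- NA_real_
  for (p in p_grid) {
    nu <- p * lambda_c * base$delta
    if (nu > 1) {
      stop("SIS calibration: nu above 1 at p = ", p, call. = FALSE)
    }
    cfg <- base
    cfg$nu <- nu
    dens <- numeric(n_replicates)
    ok <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg$rng_seed <- mix_seed(base$rng_seed, round(p * 1000), r)
      run <- simulate_sis(graph, cfg)
      ok[r] <- run$equilibrium$reached && run$equilibrium_density > 0
      dens[r] <- run$equilibrium_density
    }
    if (is.na(p_hat) && mean(ok) > 0.5) p_hat <- p
    if (!is.na(p_hat) && mean(dens) >= density_fraction) {
      return(list(lambda_hat = p_hat * lambda_c,
                  lambda_star = p * lambda_c,
                  p_hat = p_hat, p_star = p, lambda_c = lambda_c))
    }
  }
  stop("SIS calibration: grid exhausted without reaching the density ",
       "criterion (last p tried: ", p_grid[length(p_grid)], ")",
       call. = FALSE)
}

#' SIS ground truth: node persistence at equilibrium
#'
#' Averages per-node persistence over `config$n_simulations` independent
#' [simulate_sis()] runs (each on a derived RNG stream) and ranks nodes
#' by the averaged values. Runs that go extinct contribute zero
#' persistence; use a spreading rate at or above the calibrated
#' lambda-star so extinction is rare.
#'
#' @param graph An undirected igraph graph.
#' @param config An [sis_config()].
#' @return An object of class `ground_truth` with `kind`
#'   `"sis_persistence"`.
#' @export
sis_ground_truth <- function(graph, config) {
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  acc <- numeric(n)
  for (i in seq_len(config$n_simulations)) {
    cfg <- config
    cfg$rng_seed <- mix_seed(config$rng_seed, i)
    acc <- acc + simulate_sis(graph, cfg)$persistence
  }
  values <- stats::setNames(acc / config$n_simulations,
                            igraph::V(graph)$name)
  new_ground_truth("sis_persistence", values, config, config$n_simulations,
                   config$rng_seed)
}
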