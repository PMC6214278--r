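# maxrd

Identify the influential spreaders of a complex network **without
access to the full graph**, from exploration samples alone.

The influential spreaders are the nodes that, once infected or
informed, drive the largest epidemics or information cascades. The
standard identifiers — k-core decomposition, betweenness — are global
measures that need the whole graph. `maxrd` implements a
graph-exploration sampling method, **maxRD** (max rank-degree), that
discovers a 20% sample of the network by repeatedly crossing the edge
to each current node's maximum-*residual*-degree neighbour (degree in a
working copy from which crossed edges are removed), plus the full
harness needed to evaluate it:

* **Samplers** — maxRD, Forest Fire, Metropolis–Hastings random walk,
  and the centralized Metropolis–Hastings degree-distribution sampler,
  all returning reproducible samples with provenance.
* **Epidemic ground truth** — discrete-time SIR and SIS simulators.
  SIR spreading efficiency $M_i$ is the expected outbreak size seeded
  at node $i$; SIS persistence $\rho_i$ is the long-run infection
  frequency of $i$ at the endemic equilibrium. Thresholds
  $T^c = \langle k\rangle/(\langle k^2\rangle - \langle k\rangle)$ and
  $\lambda^c = \langle k\rangle/\langle k^2\rangle$ come from the first
  two degree moments, and calibration scans
  $T = p \times T^c$ ($\lambda = p \times \lambda^c$), $p = 1, 1.1,
  \ldots$ locate the smallest usable epidemic parameters on the finite
  network as it is.
* **Evaluation** — imprecision
  $\varepsilon(\text{top-}k) = 1 - \bar M_C/\bar M_{eff}$,
  persistence-distance $\delta\rho = 1 - \bar\rho_C/\bar\rho_{eff}$,
  overlap similarity $OSim = |A \cap B|/k$, and a top-k Kendall tau
  that compares a candidate's top-k ordering with the ordering those
  same nodes have in the ground truth, over the top-k grid 1%…10%.
* **Synthetic fixtures** — graph families with closed-form degree
  moments, thresholds, core numbers and component sizes, so the whole
  pipeline is testable without external downloads.

Graphs are plain undirected `igraph` objects read from whitespace
edge-list files (`#` comments; directed input is symmetrized,
self-loops dropped).

## Worked example

Sample a 500-edge preferential-attachment network at 20%, build an SIR
ground truth at the calibrated epidemic parameter, and score sampled
rankings against the full-information case:

```r
library(maxrd)

g   <- make_fixture("barabasi_albert", n = 300, m = 3, rng_seed = 1)$graph
mom <- degree_moments(g)
mom
#> degree moments: <k> = 5.96, <k^2> = 64.16
sir_threshold(mom)
#> [1] 0.1024  (rounded)

cal <- calibrate_sir(g, sir_config(beta = 0, n_simulations = 20, rng_seed = 2))
cal$p; cal$t_star
#> [1] 1        # the theoretical threshold already passes the criterion
#> [1] 0.1024

gt  <- sir_ground_truth(g, sir_config(beta = cal$beta, n_simulations = 100,
                                      rng_seed = 3))
rep <- run_experiment(g, "maxrd", sampler_config(rng_seed = 4),
                      ground_truth = gt, measures = c("degree", "kcore"),
                      n_samples = 20, rng_seed = 5)
subset(summary(rep), statistic %in% c("imprecision", "osim") & top_k == 0.05)
#>  source measure top_k   statistic       mean         sd n_missing
#>   graph  degree  0.05 imprecision 0.05100464         NA         0
#>  sample  degree  0.05 imprecision 0.06659520 0.02286732         0
#>   graph   kcore  0.05 imprecision 0.69506905         NA         0
#>  sample   kcore  0.05 imprecision 0.21154211 0.05012602         0
#>   graph  degree  0.05        osim 0.80000000         NA         0
#>  sample  degree  0.05        osim 0.79333333 0.05681611         0
#>   graph   kcore  0.05        osim 0.00000000         NA         0
#>  sample   kcore  0.05        osim 0.51000000 0.09496075         0
```

Reading the top-5% rows: degree rankings computed in 20% maxRD samples
identify spreader sets essentially as efficient as full-information
degree (imprecision 0.067 vs 0.051, overlap with the true top-5% 0.79
vs 0.80). The k-core rows illustrate a property of pure
preferential-attachment graphs: every node has core number `m`, so the
full-information k-core ranking is a coin flip (OSim 0) while the
*sampled* k-core, computed on the thinned subgraph, recovers some
signal — on heavy-tailed graphs with a real core hierarchy (see the
`power_law` fixture family) full-information k-core is instead a
strong baseline. The methods vignette
(`vignettes/maxrd-methods.Rmd`) covers the models, the calibration
protocol, and all design decisions.

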