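---
title: "Identifying influential spreaders from graph samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying influential spreaders from graph samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The influential spreaders of a network are the nodes that, once
infected (or informed), drive the largest epidemics (or cascades of
information). Identifying them normally requires global measures —
k-core decomposition, betweenness — computed on the full graph. For
large or access-restricted networks (online social networks crawled
through an API, say) the full graph is not available, and the question
becomes: *can the influential spreaders be identified from a sampled
subgraph alone?*

This package implements a graph-exploration answer, the **maxRD**
(max rank-degree) sampler, together with the machinery needed to
evaluate it: reference samplers, discrete-time SIR/SIS epidemic
simulators that define a ground-truth ranking of spreading efficiency,
threshold calibration, and top-k comparison statistics.

## The maxRD sampler

Given an undirected simple graph $G(N, E)$, maxRD starts $s$ parallel
traverses from $s$ uniformly drawn seed nodes. Each round, every
current seed $i$ selects the neighbour $j$ with the largest *residual
degree* — its degree in a working copy of the graph from which all
previously crossed edges have been removed — the edge $\{i, j\}$ is
crossed (and removed from the working copy), and $j$ joins the next
seed set. Visited nodes are never removed, so a node can be revisited
along new edges, but no edge is crossed twice. The traverse halts once
the number of discovered nodes reaches the target fraction $x$ of
$|N|$ (20% in the reference setup), and the output sample is the set of
crossed edges.

The selection rule is deterministic; randomness enters only through the
initial seeds, through tie-breaks, and through *random jumps*. Three
design points were genuinely open and are resolved as follows:

* **Ranking degree.** Neighbour ranking uses the residual degree, not
  the original degree: the edge-elimination process is what makes the
  exploration adaptive, and with original degrees the walker would
  repeatedly chase the same hubs along fresh edges.
* **Tie-breaking.** Ties among equally ranked neighbours are broken by
  a uniform draw from the sampler's seeded RNG. Breaking ties by node
  id would bias exploration toward whatever the file ordering happens
  to be; the seeded draw keeps runs reproducible (`rng_seed` is part of
  the sample's provenance).
* **Jump trigger.** The random jump is the escape hatch for a stuck
  walker. We trigger it when *no current seed has any remaining
  incident edge in the working copy* — the only condition under which
  the walker literally cannot move — and re-seed with $s$ fresh nodes
  drawn from the not-yet-discovered set (which guarantees progress and
  termination for any target fraction up to 1). The trigger condition
  is sometimes described as "all seeds have degree one"; a seed with
  one remaining edge can still cross it, so we read that as an
  off-by-one description of exhaustion.

With a fixed seed, a maxRD run is bit-identical across repetitions, and
on a fixture whose residual-degree choices are strictly ordered the
whole trace is independent of the RNG — both properties are frozen in
the test suite against a hand-simulated trace.

## Reference samplers

**Forest Fire** burns outward from a random node: each frontier node
chooses $x \sim \mathrm{Geom}$ (support $\{0, 1, \ldots\}$, mean
$p_f/(1-p_f)$, default $p_f = 0.7$) unburned incident edges uniformly
at random; burned nodes are never revisited; a dead fire restarts from
a fresh unburned node. The mean is sometimes printed as
$p_f(1-p_f)$; we follow the standard formulation $p_f/(1-p_f)$ of the
method's original description and treat the other form as a slip.

**Metropolis–Hastings random walk (MHRW)** runs $s$ parallel walks; a
proposed move $x \to y$ (uniform neighbour) is accepted with
probability $\min(1, \deg(x)/\deg(y))$ using original-graph degrees,
which makes the stationary distribution uniform over nodes. Rejected
proposals cross no edge. On multi-component graphs individual walks may
be trapped; starting $s = 1\%$ of $|N|$ walks mitigates this.

**Metropolis–Hastings (MH)** is the one centralized sampler (it sees
the whole graph). It starts from a uniform node subset of the target
size and proposes single-node swaps for a fixed number of iterations
(20,000–30,000 in the reference setup). The quality function is the
$L_1$ distance between the normalized degree histograms of the induced
subgraph and the original graph; improving swaps are accepted, and
worsening swaps with probability $\Delta_{old}/\Delta_{new}$. The
original description of this sampler leaves the exact objective and
acceptance temperature open; both the distance and the acceptance rule
are package decisions and are isolated in the code so they can be
swapped.

All sample-based centralities are computed on the *sample subgraph*:
the crossed edges plus the discovered nodes (seeds that never crossed
an edge appear isolated).

## Epidemic ground truth

### SIR

Discrete-time synchronous SIR: each period, every infected node
independently infects each susceptible neighbour with probability
$\beta$, then recovers with probability $\gamma$ (fixed at 1 in the
reference protocol). The spreading efficiency $M_i$ of node $i$ is the
number of ever-infected nodes (the seed counts, so $M_i \in [1, |N|]$)
when the epidemic starts at $i$ alone. The ground truth averages $M_i$
over `n_simulations` instances, each instance being $|N|$ trials (one
per seed node).

Two ordering conventions inside a period matter and are fixed as:
infections are evaluated before recoveries, and newly infected nodes
neither transmit nor recover until the next period. With $\gamma = 1$
any other order would either make transmission impossible or give nodes
two infectious periods. Under this convention and $\gamma = 1$ the
process is exactly equivalent to bond percolation with occupation
probability $\beta$ — each edge out of an infected node is tried
exactly once — which the tests exploit as an exhaustive oracle on small
graphs, and $\beta = 1$ sweeps exactly the seed's connected component.

The epidemic threshold is $T^c = \langle k\rangle / (\langle k^2\rangle
- \langle k\rangle)$ with $T = \beta/\gamma$ the control parameter; the
moments are taken over all nodes of the graph as given (no
largest-component extraction — multi-component graphs are studied as
they are, which is also why the threshold is *calibrated* rather than
used directly).

### SIS

Discrete-time synchronous SIS with infection probability $\nu$ and
recovery probability $\delta$ (fixed at 0.8), effective spreading rate
$\lambda = \nu/\delta$, threshold $\lambda^c = \langle k\rangle /
\langle k^2\rangle$. Runs start with 20% of nodes infected. A node
infected this period cannot recover this period.

The endemic equilibrium is detected from the infected-count increments
$\Delta(I) = I(t{+}1) - I(t)$: early increments are negative; after the
first $\Delta(I) \ge 0$ the system rests for `rest_periods` (100)
periods, then increments are accumulated until at least
`window_periods` (100) of them average within `tolerance` of zero.
"Close to zero" is not a number in the protocol's source; the default
tolerance is 0.5 nodes per period, i.e. over a 100-period window the
net gain or loss is under 50 infections on graphs of thousands of
nodes — configurable. After equilibrium, node persistence $\rho_i$ is
the fraction of a `measure_periods` (default 100, matching the
protocol's own window scale) measurement window during which $i$ is
infected. Extinction before equilibrium is a legitimate outcome (it is
precisely what the $\hat\lambda$ scan must observe below threshold) and
is returned as an all-zero, flagged result, not an error; only
exceeding the safety cap `max_periods` raises one. Persistence values
are averaged over `n_simulations` independent runs (the protocol's
source does not say whether one long run or many are used; averaging
independent runs is the variance-reducing choice and reduces to a
single run by configuration).

### Calibration

The ground-truth ranking is only informative just above the *effective*
threshold of the finite network, which the theoretical formula can
misstate. Both models are calibrated by scanning $p = 1, 1.1, 1.2,
\ldots$:

* **SIR**: $T^\ast = p \times T^c$ is the smallest grid value for which
  in *every* simulation instance the top-20% most efficient nodes have
  mean efficiency strictly larger than 1% of $|N|$.
* **SIS**: $\hat\lambda$ is the smallest grid value whose runs reach a
  non-zero-density equilibrium (judged over replicates by majority);
  $\lambda^\ast \ge \hat\lambda$ is the smallest with mean equilibrium
  density at least 1% (extinct replicates count as density zero).

The strict ">" for SIR and "$\ge$" for SIS follow the protocol's
wording. Note that at exactly $p = 1$ a homogeneous graph (e.g. a
complete graph, where $\lambda^c = 1/(n-1)$ is exact) sits *at*
criticality, where stochastic extinction is common — grid scans on such
fixtures legitimately return $p > 1$.

## Evaluation statistics

For a top-k fraction (grid 1%…10% of the *original* graph's $|N|$,
$k = \max(1, \mathrm{round}(f \cdot |N|))$ — the rounding convention is a
package decision):

* **Imprecision** $\varepsilon = 1 - \bar M_C / \bar M_{eff}$, the
  relative shortfall of the candidate top-k's mean ground-truth
  efficiency against the ground-truth top-k's own mean;
  **persistence-distance** is the SIS analogue on $\rho$. Both are 0
  exactly when the candidate's top-k value multiset matches the ground
  truth's, and always in $[0, 1)$.
* **OSim** $= |A \cap B| / k$, order-insensitive overlap of the two
  top-k sets.
* **Top-k Kendall tau**: list $A$ is the candidate's top-k in candidate
  order; list $B$ is *the same k nodes* ordered by their ground-truth
  values regardless of their global ground-truth positions (a sample's
  top-k need not be in the ground truth's top-k). The default is the
  tie-adjusted tau-b (computed via `stats::cor`), because degree and
  especially k-core scores tie heavily; tau-a is selectable, and the
  report carries the tie fraction of each candidate top-k so fragile
  tau values can be recognized.

Ranking ties are broken by a seeded uniform shuffle within tie groups
(`rank_nodes()`), surfaced in the `tie_policy` field: with coarse
scores, tie handling materially moves OSim, so it must be explicit and
reproducible rather than an accident of sort stability.

If a sample discovers fewer than $k$ nodes, that (sample, top-k) cell
is recorded as missing and excluded from averages, with the missing
count reported — undersized samples are never padded.

## The synthetic fixture generator

`make_fixture()` produces graphs with closed-form expectations
(asserted at generation time): $k$-regular graphs
($T^c = 1/(k{-}1)$, $\lambda^c = 1/k$, all cores $k$), stars, paths,
complete graphs, disjoint unions with known component sizes, and two
random families — Erdős–Rényi and heavy-tailed graphs.

The heavy-tailed families stand in for the real social, collaboration
and peer-to-peer networks of the reference study, whose
spreader-identification signal rests on degree heterogeneity. Two
families are provided because they emulate different aspects:

* **Barabási–Albert** (`barabasi_albert`, default end-to-end fixture):
  heavy-tailed degrees, but its core decomposition is degenerate —
  every node has core number exactly $m$, a known property of pure
  preferential attachment. On such a graph a full-information k-core
  ranking is a pure tie shuffle, so BA fixtures exercise degree-based
  identification only.
* **Static power-law** (`power_law`, fitness model, default exponent
  2.0): non-degenerate core hierarchy whose innermost shells are small
  (tens of nodes at $n = 500$), like real social networks — the fixture
  of choice whenever k-core must carry signal.

Neither family reproduces community structure, clustering, degree
assortativity or the precise shell profiles of real networks, so
passing tests on them demonstrate correctness of the machinery and the
direction of the qualitative effects, not the quantitative accuracy
achievable on any particular real network.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the full pipeline at
reduced scale, chosen so the Monte-Carlo signal is decisive while the
suite stays quick: 500-node fixtures, 100 ground-truth instances, 20
samples per sampler, and calibration scans with 20 instances per grid
point. The reference protocol's full scale (1000 instances, 100
samples, networks of $10^3$–$10^5$ nodes) is reachable through the same
functions by raising the configuration values.

RNG handling: every randomized operation takes an explicit integer seed
and restores the caller's RNG state; per-trial streams are derived from
(master seed, instance, seed node) with an exact integer hash, so the
$|N|$-trial sweeps are reproducible and could be parallelized without
changing results. Degenerate inputs are policed at the boundaries:
empty graphs cannot be sampled or summarized, a perfect matching
($\langle k^2\rangle = \langle k\rangle$) has no SIR threshold, an
all-tied ground truth makes tau-b undefined (`NA`), and a zero
ground-truth top-k mean makes the distance statistics undefined
(error).

## Known limitations

* Betweenness is exact (no pivot sampling); on graphs beyond ~$10^5$
  edges it is the slowest centrality by far.
* The MH sampler's objective follows one published strategy
  (degree-histogram $L_1$); other strategies from the same family are
  not implemented.
* Continuous-time (Gillespie) epidemic dynamics, per-edge heterogeneous
  rates, and directed or weighted graphs are out of scope.
* The simulators are plain R; they are comfortable at fixture scale
  ($10^4$–$10^5$ trials on 500-node graphs in seconds) but a
  full-scale reproduction on $10^5$-node networks would benefit from a
  compiled inner loop.
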