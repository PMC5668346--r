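---
title: "Diverse clubs, rich clubs, and selection for modular efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse clubs, rich clubs, and selection for modular efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diverseclub)
library(igraph)
```

## The two clubs

Complex networks -- nervous systems, transportation systems, power
grids -- are modular: their nodes divide into communities that are
densely connected inside and sparsely connected between. Integration
across communities is carried by hub nodes, and there are two distinct
ways a node can be a hub.

A node's **strength** $k_i = \sum_j A_{ij}$ is the sum of its incident
edge weights (its degree, for binary graphs). The set of nodes at or
above a high strength percentile is the **rich club**.

A node's **participation coefficient**
$$\mathrm{PC}_i = 1 - \sum_{s=1}^{N_M} \left(\frac{K_{is}}{K_i}\right)^2$$
measures how evenly its edge weight is spread over the $N_M$
communities of a partition: $K_{is}$ is the weight node $i$ sends into
community $s$. PC is 0 when all edges stay within one community and
approaches its maximum $1 - 1/N_M$ at perfectly even spread. The set
of nodes at or above a high PC percentile is the **diverse club**. PC
is independent of strength by construction: redistributing a node's
fixed-weight edges across communities changes PC without changing
$k_i$.

Because PC depends on the partition, every diverse-club analysis is
conditional on a community-detection algorithm and its parameters.
`detect_communities()` exposes nine algorithms through one interface
(all delegated to igraph): InfoMap, Louvain, Louvain with a resolution
parameter, leading-eigenvector (spectral), label propagation, edge
betweenness, spin glass, Walktrap, and Walktrap-N (the Walktrap
dendrogram cut to a requested number of communities, or to as many as
the recorded merges allow, whichever comes first). `sweep_partitions()`
runs an algorithm over a grid -- typically graph densities for
functional (correlation-derived) networks, or repeated seeded runs for
structural ones. Edge betweenness always receives a binarized copy of
the graph: with weighted shortest paths a strong edge would count as a
*long* distance, which is the wrong reading for these networks. PC is
always computed from the weighted graph, whatever copy the detector
saw.

## Clubness and its null

How interconnected is a club? For a club of $n_c$ nodes whose mutual
edges have total weight $e$,
$$\theta = \frac{e}{n_c (n_c - 1)/2},$$
the density of the club's induced subgraph (weighted in the numerator).
Raw $\theta$ is confounded by the degree sequence -- high-strength
nodes are interconnected in almost any graph -- so it is normalized by
the mean clubness $\theta_{\mathrm{rand}}$ of the *same node set* in an
ensemble of degree-preserving randomized graphs:
$$\theta_{\mathrm{norm}} = \theta / \theta_{\mathrm{rand}}.$$
Values above 1 mean the club is more interconnected than its members'
degrees alone would produce. A supplementary variant normalizes by the
null standard deviation, $(\theta - \theta_{\mathrm{rand}})/\mathrm{sd}$;
both are reported by `normalized_clubness()` and `clubness_curve()`.

The null ensemble (`randomize()`, default 1000 members) uses iterated
double-edge swaps -- at least $10m$ attempted swaps per member -- which
preserve every node's degree exactly. Weights travel with their edges.
An optional second mode additionally shuffles weights among edges whose
unordered endpoint-degree pairs match, randomizing the weight-to-edge
assignment while leaving the weight-degree relation intact. Topology-only
nulls are the default; the weight shuffle is an optional extra, and on
binary graphs the two coincide.

Graphs are plain igraph objects: undirected, simple, positive weights.
`load_graph()` reads edge-list TSV, symmetric matrix CSV (tolerance
1e-8; negative entries, e.g. negative correlations, are dropped or
rejected by policy), and GraphML. `threshold_graph()` sparsifies
weighted graphs to a target cost (fraction of possible edges, budget
$\lfloor \mathrm{cost} \cdot n(n-1)/2 \rfloor$) while always retaining
the maximum spanning tree so the graph stays connected; weight ties at
the cutoff break by node-pair order, so thresholding is deterministic.
Density sweep bounds (e.g. 0.05--0.15 or 0.05--0.20 in 0.01 steps) are
left as configuration rather than fixed, since different network types
warrant different ranges.

## Clubs at every rank

```{r clubs, eval = FALSE}
pp <- planted_partition(blocks = 4, block_size = 15, p_in = 0.8,
                        p_out = 0.003, bridge_nodes = 8,
                        bridge_degree = 4, seed = 11)
g <- pp$graph
p <- detect_communities(g, "infomap", seed = 1)
pc  <- participation_coefficient(g, p)
str <- node_strength(g)
ens <- randomize(g, size = 1000, seed = 5)
diverse_curve <- clubness_curve(g, pc, ens, metric = "participation")
rich_curve    <- clubness_curve(g, str, ens, metric = "strength")
```

A club at rank $r$ over $n$ nodes contains the nodes whose metric is at
or above the $(n-r)$-th highest value; ties at the cutoff are all
included, so a club can exceed its nominal size (common for integer
strengths on binary graphs). The percentile form used for the headline
comparisons is the 80th percentile, giving
$\lceil 0.2\,n \rceil$ members absent ties -- 53 nodes for a 264-node
network. `club_overlap()` (percentage of possible overlap, with the
smaller club as denominator so that 100 still means identical when ties
unbalance the sizes), `community_coverage()`, `club_betweenness()` and
`intra_club_edge_betweenness()` quantify how the two clubs differ
topologically. The betweenness comparisons use a two-sided Welch test
with a Cohen's d effect size -- a choice this package makes explicit,
since "significantly higher" does not name a test -- and all
shortest-path quantities use binarized graphs.

## Lesions

`lesion_club()` simulates damage to a club's internal wiring: per
iteration it draws a removal fraction uniformly from 50--90% of the
intra-club edges, shuffles those edges, and removes them one at a time,
skipping any removal that would split the graph -- the per-edge skip
guarantees progress and keeps the lesioned graph connected, so the
efficiency loss is always well defined. The outcome is the increase in
the all-pairs binary path sum. The removal fraction is sampled per
iteration rather than swept, matching the "between 50 and 90%" reading.
On fixtures with a designed diverse club (below), lesioning diverse-club
edges costs more efficiency than lesioning rich-club edges, because
those edges carry inter-community shortest paths.

Efficiency is carried as the negated path sum,
$E = -\sum_{i<j} d(i,j)$ -- larger is better. The companion phrase "the
inverse of the sum of shortest paths" agrees with the negation in
ordering but not in value; this package implements the negated form
throughout, and every use of $E$ is a comparison, so the distinction
never affects a result.

## The generative evolutionary model

Why would a network evolve a diverse club? The model asks which club
emerges when a network is selected for being simultaneously modular
(high $Q$) and integrated (high $E$):

$$Q = \frac{1}{2m}\sum_{i \ne j}\left(A_{ij} - \gamma\,
\frac{k_i k_j}{2m}\right)\delta(c_i, c_j)$$

with the $i \ne j$ restriction applied to the null term as printed
(the diagonal $k_i^2$ products are excluded, a small but deliberate
difference from formulations that keep them; `modularity_q()` is tested
against a literal double-summation oracle).

A run starts from a connected random binary graph of 100 nodes and 247
edges (density 0.05; $G(n,m)$ draws are resampled until connected,
since $E$ is undefined otherwise and is evaluated at every iteration).
Each of 150 iterations:

1. detect communities (InfoMap by default; see below), and record $Q$
   and $E$;
2. for every edge, compute $\Delta Q$ and $\Delta E$ of its removal
   (partition held fixed, so $\Delta Q$ is a pure closed-form function
   of the edge);
3. competition-rank the two change vectors ascending (ties get the
   minimum spanned rank), z-score the ranks (population SD; an all-tied
   vector becomes zeros), and combine them as
   $q\cdot z_Q + (1-q)\cdot z_E$ with the Q-ratio $q \in [0.5, 1]$;
4. remove the 13 highest-scoring edges (edges whose removal would
   disconnect the graph score $-\infty$ and the removals are applied
   sequentially with the same skip rule as lesions);
5. add 13 edges back uniformly at random among absent pairs -- possibly
   restoring a removed edge -- keeping density constant.

Over 150 iterations, $13 \times 150 = 1950$ edges are shuffled. The
default Q-ratio is 0.75, the regime where clubness, efficiency and
distribution fits balance. The random-selection null (`run_null()`)
replaces step 2--4 with uniform random edge choice.

**Which partitioner runs inside the model?** The model's description
does not name one, so this was an open design choice. Louvain
(resolution 1) turned out to keep consolidating the community structure
well past iteration 150: the windowed change of the ensemble-mean $Q$
stayed near 1.5%. InfoMap -- the algorithm used for all headline club
analyses -- equilibrates by roughly iteration 80 and brings the final-30
windowed change of both $Q$ and $E$ under 1%, which is the model's
stated convergence criterion. InfoMap is therefore the default, with
Louvain available via `model_config(algorithm = "louvain")`.

Convergence is checked by `stability_diagnostics()`: average the $Q$
and $E$ series across runs, compare each of the last 30 iterations
against each of its 40 predecessors as an absolute percentage of the
current value, and require the mean below 1%. The percentage is taken
relative to the current iteration's value (so a series that doubles
each step changes by 50% per single-step comparison).

`kld_fit()` measures how well a model network's degree or PC
distribution matches a user-supplied reference vector: both vectors are
binned into 10 equal-width bins spanning their pooled range and
$\sum_i P(i)\log(P(i)/K(i))$ is returned (natural log; an empty
reference bin under model mass makes the divergence infinite, which is
reported as `Inf` with a warning). Shared pooled-range bin edges were
chosen because per-distribution edges would make identical distributions
compare unequal. Fitting to empirical human brain distributions is out
of scope; any reference vector can be supplied.

`compare_model_vs_null()` closes the loop: for every final graph of the
model and null ensembles it detects communities, builds the strength
and PC rankings, and evaluates normalized clubness against a
degree-preserving null of that graph, returning per-rank ensemble means
and Welch t statistics. Under joint $Q$/$E$ selection the diverse club's
clubness at the top fifth of ranks sits clearly above the random
model's, while the rich club shows no such elevation -- selection for
modular efficiency produces a diverse club, not a rich club. Evaluation
seeds derive from each trace's own seed, so a given run is always
evaluated identically.

## What the synthetic generators emulate

No external data ship with the package; every analysis is exercised on
synthetic graphs:

* `planted_partition()` -- a stochastic block graph (default 4 blocks
  of 15, $p_{in} = 0.8$, $p_{out} = 0.05$, strong enough that all nine
  algorithms recover the blocks exactly) plus optional **bridge
  nodes**: extra nodes whose edges are spread evenly over all blocks
  and which are fully interconnected among themselves. The bridges are
  a designed diverse club -- high PC by construction, mutual edges
  carrying inter-community shortest paths. The designed-club
  demonstrations lower $p_{out}$ to 0.003 and keep the bridges'
  block-directed degree moderate, so that inter-block traffic genuinely
  depends on the bridge edges while the bridges stay below the
  strength cutoff -- the two clubs then separate cleanly.
* `er_graph()` -- $G(n, m)$ with exactly
  $\lfloor \mathrm{density}\cdot n(n-1)/2\rfloor$ edges (sampled
  without replacement rather than per-pair Bernoulli, so stated edge
  counts like 247 are exact).
* `ring_lattice()` -- deterministic $2k$-regular ring.

These fixtures reproduce the *qualitative* club phenomena -- diverse
clubs that out-club rich clubs, bridge edges that are critical to
efficiency -- but they are not brain-like: real correlation networks
have heavy-tailed strength distributions, geometric constraints and
noise structure the block model lacks. Passing tests on these fixtures
validates the machinery and the direction of the effects, not any
empirical magnitude.

## Numerical choices and scale

* All randomness flows through one seeded generator per operation
  (`seed` arguments); fixed seeds give bit-identical outputs, and the
  caller's RNG state is never disturbed.
* Zero-strength nodes get PC = 0 (with a warning) so club rankings stay
  total.
* Clubness curves report a rank as missing rather than failing when its
  club has fewer than 2 members or its null mean is 0.
* Degenerate rank vectors (all values tied) z-score to zeros rather
  than NaN.
* The per-edge $\Delta E$ scoring runs in compiled code: a BFS kernel
  computes all-pairs path sums for the graph and all single-edge
  removals in one call, skipping every source whose distance row
  provably cannot change (the removed edge must be the unique parent
  link of its farther endpoint). It is tested against explicit
  edge-by-edge deletion.
* Ensemble sizes in the test suite are desk-scale choices: 100-run
  model ensembles (full-scale analyses would use 1000), 100-member
  clubness nulls inside the model-vs-null comparison, and 1000-member
  nulls elsewhere. The orderings tested are insensitive to these
  sizes; the Q convergence scalar is the one quantity that sits near
  its 1% threshold at desk scale, because the ensemble-mean Q retains
  a slow consolidation trend of about that size over the final
  window.

## Limitations

* Directed graphs are not supported; inputs are treated as undirected.
* The stability-optimizing multi-scale Louvain variant is approximated
  by Louvain's resolution parameter; exact equivalence is not claimed.
* Statistical comparison of clubness curves *across* detection
  algorithms is out of scope (results are grouped per algorithm).
* The generative model's dynamics beyond 150 iterations (e.g. the slow
  continued rise of $E$) are faithfully reproducible but not analyzed
  further here.
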