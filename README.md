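# diverseclub

Network hubs come in two kinds. A node can be a hub because it has
many (or heavy) connections — high **strength** — or because its
connections are spread evenly across the network's communities — a
high **participation coefficient**. The high-strength nodes form the
**rich club**; the high-participation nodes form the **diverse club**.
The two clubs are mostly different nodes with different topological
roles, and across biological and man-made networks it is the diverse
club, not the rich club, that is densely interconnected relative to
chance and critical for efficient inter-community communication.

`diverseclub` implements this analysis framework for undirected
weighted or binary graphs:

* **Node metrics** — strength $k_i = \sum_j A_{ij}$ and participation
  coefficient $\mathrm{PC}_i = 1 - \sum_s (K_{is}/K_i)^2$, where
  $K_{is}$ is the weight node $i$ sends into community $s$.
* **Clubs and clubness** — clubs by rank or percentile of either
  metric; clubness $\theta = e / \binom{n_c}{2}$ (intra-club weight
  over possible intra-club pairs), normalized as
  $\theta_{\text{norm}} = \theta / \theta_{\text{rand}}$ against
  degree-preserving double-edge-swap null ensembles, across all ranks
  (`clubness_curve()`); club overlap, community coverage, and node /
  edge betweenness comparisons.
* **Lesion simulations** — random removal of 50–90% of intra-club
  edges (never disconnecting the graph) and the resulting increase in
  the all-pairs shortest-path sum.
* **A generative evolutionary model** — starting from a random graph
  (100 nodes, 247 edges), edges whose removal jointly maximizes
  modularity $Q$ and efficiency $E = -\sum_{i<j} d(i,j)$ are removed
  and randomly re-placed, 13 per iteration for 150 iterations, with a
  Q-ratio parameter weighting the two objectives; plus a
  random-selection null, convergence diagnostics, binned
  Kullback–Leibler distribution fits, and a model-vs-null clubness
  comparison. Under joint selection a diverse club emerges; a rich
  club does not.
* **Community detection** — one interface to nine igraph algorithms
  (InfoMap, Louvain, Louvain-resolution, spectral, label propagation,
  edge betweenness, spin glass, Walktrap, Walktrap-N) with parameter
  sweeps over densities, resolutions, community counts, or runs.
* **Synthetic fixtures** — planted partitions with designed
  high-participation "bridge" nodes, exact-edge-count Erdős–Rényi
  graphs, ring lattices.

Graphs are plain [igraph](https://r.igraph.org) objects (undirected,
simple, positive `weight` attribute). Input formats: edge-list TSV,
symmetric matrix CSV, GraphML.

## Worked example

```r
library(diverseclub)

# A modular graph with 8 designed bridge nodes: edges spread evenly
# over the 4 blocks, bridges interconnected among themselves.
pp <- planted_partition(blocks = 4, block_size = 15, p_in = 0.8,
                        p_out = 0.003, bridge_nodes = 8,
                        bridge_degree = 4, seed = 11)
g <- pp$graph

p   <- detect_communities(g, "infomap", seed = 1)
pc  <- participation_coefficient(g, p)
str <- node_strength(g)

diverse <- make_club(pc,  percentile = 80, metric = "participation")
rich    <- make_club(str, percentile = 80, metric = "strength")
club_overlap(diverse, rich)
#> [1] 28.57143

ens <- randomize(g, size = 1000, seed = 5)
normalized_clubness(g, diverse, ens)$theta_norm
#> [1] 2.503912
normalized_clubness(g, rich, ens)$theta_norm
#> [1] 0.9134088

# Intra-club lesions: diverse-club edges are the critical ones
mean(lesion_club(g, diverse, iterations = 200, seed = 2)$delta_path_sum)
#> [1] 430.705
mean(lesion_club(g, rich, iterations = 200, seed = 3)$delta_path_sum)
#> [1] 153.095
```

The diverse club is about 2.5 times more interconnected than its
degree-preserving null, while the rich club sits at chance (0.91) — and
removing diverse-club edges costs far more global efficiency than
removing rich-club edges.

The generative model:

```r
trace <- run_model(model_config(q_ratio = 0.75, seed = 42))
trace
#> Generative model trace (selection model)
#>   100 nodes, 247 edges, 150 iterations, q_ratio 0.75
#>   Q: 0.439 -> 0.647;  E: -14955 -> -14595
```

Modularity and efficiency both rise under selection; the
random-selection null (`run_null()`) stays flat.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "diverseclub", package = "diverseclub"))')" \
  clubs --graph network.tsv --format edgelist --algorithm infomap \
  --percentile 80 --nulls 1000 --seed 1 --out results/
```

Subcommands: `clubs`, `lesion`, `genmodel`, `communities`, `synth`.
Every run writes a JSON manifest (command, parameters, seed, input
digest, outputs, timestamp) alongside its result files.

## Documentation

The methods vignette (`vignettes/diverse-club-analysis.Rmd`) explains
the model, its assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the numerical choices
made throughout.
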