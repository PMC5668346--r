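# Shared fixtures, built in code. Heavy objects are computed once per
# test session and cached.

.dc_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.dc_test_cache[[key]])) .dc_test_cache[[key]] <- expr
  .dc_test_cache[[key]]
}

# Two 5-cliques joined by a single edge between nodes 5 and 6.
two_cliques <- function(clique_size = 5) {
  g <- igraph::make_full_graph(clique_size) +
    igraph::make_full_graph(clique_size)
  g <- igraph::add_edges(g, c(clique_size, clique_size + 1))
  as_club_graph(g)
}

two_cliques_partition <- function(clique_size = 5) {
  partition(setNames(rep(1:2, each = clique_size),
                     as.character(seq_len(2 * clique_size))),
            algorithm = "planted")
}

# Planted-partition fixture with interconnected bridge nodes whose
# mutual edges carry most inter-community shortest paths: a designed
# diverse club. Low p_out leaves few alternative inter-block routes.
bridge_fixture <- function() {
  cached("bridge_fixture", {
    pp <- planted_partition(blocks = 4, block_size = 15, p_in = 0.8,
                            p_out = 0.003, bridge_nodes = 8,
                            bridge_degree = 4, seed = 11)
    stopifnot(igraph::is_connected(pp$graph))
    pp
  })
}

random_weighted_graph <- function(n, density, seed) {
  withr::with_seed(seed, {
    g <- er_graph(n, density)
    while (!igraph::is_connected(g)) g <- er_graph(n, density)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 2)
    g
  })
}
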