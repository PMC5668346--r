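#' Planted-partition graph with optional designed bridge nodes
#'
#' Generates a stochastic block graph -- \code{blocks} blocks of
#' \code{block_size} nodes, within-block edge probability \code{p_in},
#' between-block probability \code{p_out} -- plus, optionally,
#' \code{bridge_nodes} extra nodes whose edges are spread evenly across
#' all blocks (\code{bridge_degree} edges each, round-robin over
#' blocks) and which are fully interconnected among themselves. The
#' bridge set is a designed diverse club: its nodes have high
#' participation coefficients by construction and their mutual edges
#' carry many inter-community shortest paths.
#'
#' @param blocks Number of blocks (default 4).
#' @param block_size Nodes per block (default 15).
#' @param p_in Within-block edge probability (default 0.8); must exceed
#'   \code{p_out}.
#' @param p_out Between-block edge probability (default 0.05).
#' @param bridge_nodes Number of designed high-participation nodes
#'   (default 0).
#' @param bridge_degree Block-directed edges per bridge node (default
#'   \code{2 * blocks}).
#' @param seed Optional integer seed; the graph is a pure function of
#'   it.
#' @return A list with \code{graph} (igraph; bridge membership in the
#'   logical vertex attribute \code{bridge}) and \code{partition} (the
#'   ground truth as a [partition()]; bridge nodes are assigned
#'   round-robin to blocks).
#' @export
planted_partition <- function(blocks = 4, block_size = 15, p_in = 0.8,
                              p_out = 0.05, bridge_nodes = 0,
                              bridge_degree = 2 * blocks, seed = NULL) {
  if (p_in <= p_out) stop("`p_in` must exceed `p_out`")
  n_block <- blocks * block_size
  with_seed_opt(seed, {
    pref <- matrix(p_out, blocks, blocks)
    diag(pref) <- p_in
    g <- igraph::sample_sbm(n_block, pref.matrix = pref,
                            block.sizes = rep(block_size, blocks))
    block_of <- rep(seq_len(blocks), each = block_size)
    if (bridge_nodes > 0) {
      g <- igraph::add_vertices(g, bridge_nodes)
      bridge_ids <- n_block + seq_len(bridge_nodes)
      for (b in seq_len(bridge_nodes)) {
        targets_block <- rep(seq_len(blocks),
                             length.out = bridge_degree)
        targets <- vapply(targets_block, function(bl)
          sample(which(block_of == bl), 1L), integer(1))
        g <- igraph::add_edges(g, rbind(bridge_ids[b], unique(targets)))
      }
      if (bridge_nodes > 1) {
        pairs <- utils::combn(bridge_ids, 2)
        g <- igraph::add_edges(g, pairs)
      }
      block_of <- c(block_of,
                    ((seq_len(bridge_nodes) - 1L) %% blocks) + 1L)
    }
    g <- igraph::simplify(g)
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$bridge <- c(rep(FALSE, n_block),
                             rep(TRUE, max(bridge_nodes, 0)))
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
    if (!igraph::is_connected(g))
      warning("planted-partition graph is disconnected at these parameters")
    list(graph = g,
         partition = partition(setNames(block_of, igraph::V(g)$name),
                               algorithm = "planted",
                               params = list(blocks = blocks,
                                             block_size = block_size,
                                             p_in = p_in, p_out = p_out,
                                             bridge_nodes = bridge_nodes)))
  })
}

#' Erdos-Renyi graph with an exact edge count
#'
#' Samples exactly \code{floor(density * n * (n - 1) / 2)} edges
#' uniformly without replacement (G(n, m), not per-pair Bernoulli), so
#' stated edge counts are exact: \code{er_graph(100, 0.05)} always has
#' 247 edges.
#'
#' @param n Number of nodes.
#' @param density Fraction of possible edges in (0, 1].
#' @param seed Optional integer seed.
#' @return A binary igraph object.
#' @export
er_graph <- function(n, density, seed = NULL) {
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  m <- floor(density * n * (n - 1) / 2)
  with_seed_opt(seed, {
    g <- igraph::sample_gnm(n, m)
    igraph::V(g)$name <- as.character(seq_len(n))
    igraph::E(g)$weight <- rep(1, m)
    g
  })
}

#' Deterministic ring lattice
#'
#' Each of the \code{n} nodes is connected to its \code{k} nearest
#' neighbors on each side of a ring, giving uniform degree \code{2k}.
#'
#' @param n Number of nodes.
#' @param k Neighbors per side.
#' @return A binary igraph object.
#' @export
ring_lattice <- function(n, k) {
  if (k < 1 || 2 * k >= n) stop("need 1 <= k and 2k < n")
  g <- igraph::make_lattice(length = n, dim = 1, nei = k,
                            periodic = TRUE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}
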