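#' Sum of binary shortest-path lengths over all node pairs
#'
#' Shortest paths are always computed on the binarized graph: edge
#' weights are presence/absence for path traversal. Global efficiency
#' is carried as the negated path sum (see [efficiency()]): the larger
#' it is, the shorter the paths.
#'
#' @param g A connected validated igraph object.
#' @return Integer-valued path sum over all unordered pairs.
#' @export
path_sum <- function(g) {
  g <- as_club_graph(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  D <- igraph::distances(g, weights = NA)   # unweighted BFS
  sum(D[upper.tri(D)])
}

#' Global efficiency (negated path sum)
#'
#' \eqn{E = -\sum_{i<j} d(i, j)} with \eqn{d} the binary shortest-path
#' length. Removing edges can only lengthen paths, so lesions always
#' decrease \eqn{E}.
#'
#' @inheritParams path_sum
#' @return The efficiency value (non-positive).
#' @export
efficiency <- function(g) -path_sum(g)

#' Simulated lesions to intra-club edges
#'
#' In each iteration a target fraction of the club's intra-club edges
#' is drawn uniformly from \code{frac_range}, the intra-club edges are
#' shuffled, and edges are removed one at a time in that order --
#' skipping any edge whose removal would disconnect the graph -- until
#' the target count is reached or no removable edge remains. The
#' increase in the all-pairs path sum relative to the intact graph is
#' recorded, and the graph is restored before the next iteration.
#'
#' @param g A connected validated igraph object.
#' @param club A [make_club()] object with at least one intra-club edge.
#' @param frac_range Length-2 numeric range of removal fractions
#'   (default \code{c(0.5, 0.9)}).
#' @param iterations Number of lesion iterations (default 10000;
#'   configurable down for desk-scale runs).
#' @param seed Optional integer seed; the outcome table is a
#'   deterministic function of it.
#' @return A data.frame with one row per iteration: \code{iteration},
#'   \code{fraction}, \code{target}, \code{removed},
#'   \code{delta_path_sum}, \code{complete} (FALSE when fewer edges
#'   than targeted could be removed without disconnection). The club
#'   metric label and seed are attached as attributes.
#' @export
lesion_club <- function(g, club, frac_range = c(0.5, 0.9),
                        iterations = 10000, seed = NULL) {
  g <- as_club_graph(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  if (length(frac_range) != 2L || frac_range[1] > frac_range[2] ||
      frac_range[1] < 0 || frac_range[2] > 1)
    stop("`frac_range` must be an increasing pair within [0, 1]")
  members <- .club_members(club, g)
  el <- igraph::as_edgelist(g)
  intra <- which(el[, 1] %in% members & el[, 2] %in% members)
  if (length(intra) == 0L) stop("club has no intra-club edges")
  base <- path_sum(g)
  rows <- with_seed_opt(seed, {
    lapply(seq_len(iterations), function(it) {
      frac <- runif(1, frac_range[1], frac_range[2])
      target <- round(frac * length(intra))
      order_ids <- sample(intra)
      gg <- g
      removed <- 0L
      for (eid_pair in order_ids) {
        if (removed >= target) break
        ends_e <- el[eid_pair, ]
        cur <- igraph::get_edge_ids(gg, ends_e)
        if (cur == 0) next
        g2 <- igraph::delete_edges(gg, cur)
        if (!igraph::is_connected(g2)) next   # skip disconnecting edges
        gg <- g2
        removed <- removed + 1L
      }
      delta <- path_sum(gg) - base
      data.frame(iteration = it, fraction = frac, target = target,
                 removed = removed, delta_path_sum = delta,
                 complete = removed >= target)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "club_metric") <- club$metric
  attr(out, "seed") <- seed
  out
}
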