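#' Node strength
#'
#' Sum of the weights of a node's incident edges; equal to degree on
#' binary graphs.
#'
#' @param g A validated igraph object.
#' @param nodes Node labels or indices; default all nodes.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(g, nodes = igraph::V(g)) {
  g <- as_club_graph(g)
  igraph::strength(g, vids = nodes, weights = igraph::E(g)$weight)
}

# n x N matrix of per-community strengths K_is.
.community_strength_matrix <- function(g, memb) {
  n <- igraph::vcount(g)
  N <- max(memb)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  K <- matrix(0, n, N)
  if (nrow(el) > 0) {
    node <- c(el[, 1], el[, 2])
    comm <- c(memb[el[, 2]], memb[el[, 1]])
    s <- rowsum(c(w, w), group = (node - 1L) * N + comm)
    key <- as.integer(rownames(s))
    K[cbind((key - 1L) %/% N + 1L, (key - 1L) %% N + 1L)] <- s
  }
  rownames(K) <- igraph::V(g)$name
  K
}

#' Participation coefficient
#'
#' For node \eqn{i} with strength \eqn{K_i} and strength \eqn{K_{is}}
#' into community \eqn{s},
#' \deqn{PC_i = 1 - \sum_s (K_{is}/K_i)^2.}
#' It is 0 when all of a node's edge weight stays within a single
#' community, and approaches its maximum \eqn{1 - 1/N_M} when the weight
#' is spread evenly over all \eqn{N_M} communities. It is computed from
#' the weighted graph regardless of whether the partition was detected
#' on a binarized copy.
#'
#' Isolated (zero-strength) nodes get PC = 0, with a warning, so that
#' club ranking over all nodes remains total.
#'
#' @param g A validated igraph object.
#' @param p A [partition()] covering the graph.
#' @param nodes Node labels; default all nodes.
#' @return Named numeric vector of participation coefficients in
#'   \eqn{[0, 1 - 1/N_M]}.
#' @export
participation_coefficient <- function(g, p, nodes = NULL) {
  g <- as_club_graph(g)
  memb <- .align_partition(p, g)
  K <- .community_strength_matrix(g, memb)
  Ki <- rowSums(K)
  pc <- numeric(length(Ki))
  pos <- Ki > 0
  pc[pos] <- 1 - rowSums((K[pos, , drop = FALSE] / Ki[pos])^2)
  if (any(!pos))
    warning("zero-strength node(s); their participation coefficient ",
            "is reported as 0")
  names(pc) <- igraph::V(g)$name
  if (!is.null(nodes)) pc <- pc[as.character(nodes)]
  pc
}

#' Per-node metric profiles
#'
#' Degree, strength, participation coefficient and community for every
#' node, as one tidy table (the vectorized equivalent of per-node
#' calls).
#'
#' @param g A validated igraph object.
#' @param p A [partition()] covering the graph.
#' @return A data.frame with columns \code{node}, \code{degree},
#'   \code{strength}, \code{participation}, \code{community}.
#' @export
node_profiles <- function(g, p) {
  g <- as_club_graph(g)
  memb <- .align_partition(p, g)
  data.frame(node = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             strength = unname(node_strength(g)),
             participation = unname(participation_coefficient(g, p)),
             community = memb,
             stringsAsFactors = FALSE)
}
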