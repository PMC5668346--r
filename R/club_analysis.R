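#' Extract a club by percentile or rank of a nodal metric
#'
#' A club is the set of nodes whose metric value (strength for the rich
#' club, participation coefficient for the diverse club) is at or above
#' a cutoff. With \code{percentile = p}, the cutoff is the value of the
#' node at the \code{(100 - p)\%} position from the top, so with no ties
#' the club holds \code{ceiling(n * (100 - p) / 100)} nodes (e.g. 53 of
#' 264 nodes at the 80th percentile). With \code{rank = r} over
#' \code{n} nodes, the club holds the nodes with value at or above the
#' \code{(n - r)}-th highest value. Nodes tied with the cutoff value are
#' all included, so the club can exceed its nominal size.
#'
#' @param metric_values Named numeric vector of the metric, one entry
#'   per node, with at least two distinct values.
#' @param percentile Percentile cutoff in (0, 100); e.g. 80.
#' @param rank Rank cutoff (alternative to \code{percentile}).
#' @param metric Label for the metric (\code{"strength"},
#'   \code{"participation"}, or any name).
#' @return An object of class \code{club}: members, metric name,
#'   threshold value, nominal size, and the node universe.
#' @export
make_club <- function(metric_values, percentile = NULL, rank = NULL,
                      metric = "metric") {
  if (is.null(names(metric_values)) || anyDuplicated(names(metric_values)))
    stop("`metric_values` must be named by unique node labels")
  n <- length(metric_values)
  if (length(unique(metric_values)) < 2L)
    stop("all metric values identical: no club separable")
  if (is.null(percentile) == is.null(rank))
    stop("supply exactly one of `percentile` or `rank`")
  if (!is.null(percentile)) {
    if (percentile <= 0 || percentile >= 100)
      stop("`percentile` must be in (0, 100)")
    k <- ceiling(n * (100 - percentile) / 100)
  } else {
    if (rank < 1 || rank > n - 2) stop("`rank` must be in [1, n - 2]")
    k <- n - rank
  }
  k <- max(k, 1L)
  thr <- sort(metric_values, decreasing = TRUE)[k]
  members <- names(metric_values)[metric_values >= thr]
  structure(list(members = members, metric = metric,
                 threshold_value = unname(thr),
                 nominal_size = as.integer(k),
                 percentile = percentile, rank = rank,
                 universe = names(metric_values)),
            class = "club")
}

#' @export
print.club <- function(x, ...) {
  cat("Club (", x$metric, "): ", length(x$members), " of ",
      length(x$universe), " nodes, threshold value ",
      format(x$threshold_value, digits = 4), "\n", sep = "")
  invisible(x)
}

.club_members <- function(club, g) {
  if (!inherits(club, "club")) stop("`club` must be a club object")
  members <- club$members
  if (!all(members %in% igraph::V(g)$name))
    stop("club members not all present in graph")
  members
}

#' Raw clubness of a node set
#'
#' The ratio between the sum of the edge weights among the club's
#' nodes, \eqn{e}, and the number of possible connections between them:
#' \deqn{\theta = e / (n_c (n_c - 1) / 2)} for a club of \eqn{n_c}
#' nodes. For binary graphs this is the density of the induced
#' subgraph.
#'
#' @param g A validated igraph object.
#' @param club A [make_club()] object with at least 2 members.
#' @return The clubness coefficient \eqn{\theta}.
#' @export
clubness <- function(g, club) {
  g <- as_club_graph(g)
  members <- .club_members(club, g)
  k <- length(members)
  if (k < 2L) stop("clubness requires at least 2 club members")
  sub <- igraph::induced_subgraph(g, members)
  e <- sum(igraph::E(sub)$weight)
  e / (k * (k - 1) / 2)
}

#' Clubness normalized by a randomized null ensemble
#'
#' Computes \eqn{\theta_{norm} = \theta / \theta_{rand}}, where
#' \eqn{\theta_{rand}} is the mean clubness of the same node set across
#' the ensemble's degree-preserving randomized graphs, together with
#' the standard-deviation-normalized variant
#' \eqn{(\theta - \theta_{rand}) / sd}. Values above 1 indicate the
#' club is more interconnected than expected from the degree sequence
#' alone. Club membership is held fixed: the identical node set is
#' evaluated in every randomized graph.
#'
#' @param g A validated igraph object.
#' @param club A [make_club()] object with at least 2 members.
#' @param ensemble A [randomize()] ensemble built from \code{g}.
#' @return List with \code{theta}, \code{theta_rand_mean},
#'   \code{theta_rand_sd}, \code{theta_norm}, \code{theta_norm_sd}.
#' @export
normalized_clubness <- function(g, club, ensemble) {
  g <- as_club_graph(g)
  if (!inherits(ensemble, "null_ensemble"))
    stop("`ensemble` must be a null_ensemble from randomize()")
  if (igraph::vcount(ensemble$source) != igraph::vcount(g) ||
      !setequal(igraph::V(ensemble$source)$name, igraph::V(g)$name))
    stop("ensemble was not built from this graph")
  theta <- clubness(g, club)
  thetas <- vapply(ensemble$graphs, function(r) clubness(r, club),
                   numeric(1))
  mu <- mean(thetas); s <- stats::sd(thetas)
  if (!is.finite(mu) || mu <= 0) {
    warning("null-ensemble mean clubness is 0; theta_norm undefined")
    norm <- NA_real_
  } else norm <- theta / mu
  list(theta = theta, theta_rand_mean = mu, theta_rand_sd = s,
       theta_norm = norm,
       theta_norm_sd = if (is.finite(s) && s > 0) (theta - mu) / s
                       else NA_real_)
}

# Clubness of every prefix of `ord` (nodes sorted by metric, descending)
# in one pass over the dense adjacency. theta_prefix[k] is theta of the
# top-k nodes; entry 1 is NA.
.theta_prefix <- function(g, ord) {
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A <- A[ord, ord, drop = FALSE]
  n <- nrow(A)
  inc <- vapply(seq_len(n), function(k)
    if (k == 1L) 0 else sum(A[k, seq_len(k - 1L)]), numeric(1))
  e <- cumsum(inc)
  k <- seq_len(n)
  theta <- e / (k * (k - 1) / 2)
  theta[1] <- NA_real_
  theta
}

#' Clubness curve across ranks, with null normalization
#'
#' Re-derives the club at every requested rank (a rank \code{r} keeps
#' the nodes with metric value at or above the \code{(n - r)}-th
#' highest; ties at the cutoff are included) and evaluates raw
#' clubness, the null ensemble's mean and SD, \eqn{\theta_{norm}} and
#' its SD-normalized variant at each rank. The same ensemble is shared
#' across all ranks. Ranks whose club has fewer than 2 members are
#' reported as missing.
#'
#' @param g A validated igraph object.
#' @param metric_values Named numeric metric vector over all nodes.
#' @param ensemble A [randomize()] ensemble built from \code{g}.
#' @param ranks Integer ranks; default \code{1:(n - 2)} ("every
#'   possible rank").
#' @param metric Metric label stored with the curve.
#' @return An object of class \code{clubness_curve}: a data.frame with
#'   columns \code{rank}, \code{club_size}, \code{theta},
#'   \code{theta_rand_mean}, \code{theta_rand_sd}, \code{theta_norm},
#'   \code{theta_norm_sd}.
#' @export
clubness_curve <- function(g, metric_values, ensemble, ranks = NULL,
                           metric = "metric") {
  g <- as_club_graph(g)
  nm <- igraph::V(g)$name
  if (!setequal(names(metric_values), nm))
    stop("`metric_values` must cover exactly the graph's nodes")
  n <- length(nm)
  if (is.null(ranks)) ranks <- seq_len(n - 2L)
  if (any(ranks < 1L | ranks > n - 1L)) stop("ranks out of range")
  v <- metric_values[nm]
  ord <- order(-v, nm)       # stable, deterministic under ties
  vs <- v[ord]
  # effective club size for nominal top-k: extend through ties at vs[k]
  k_eff_of <- cumsum(rle(as.vector(vs))$lengths)
  k_eff <- rep(k_eff_of, rle(as.vector(vs))$lengths)

  tp_g <- .theta_prefix(g, ord)
  tp_null <- vapply(ensemble$graphs, function(r) {
    ord_r <- match(nm[ord], igraph::V(r)$name)
    .theta_prefix(r, ord_r)
  }, numeric(n))
  null_mean <- rowMeans(tp_null)
  null_sd <- apply(tp_null, 1, stats::sd)

  k_nom <- n - ranks
  rows <- lapply(seq_along(ranks), function(i) {
    k <- k_eff[min(k_nom[i], n)]
    if (is.na(k) || k < 2L)
      return(data.frame(rank = ranks[i], club_size = NA_integer_,
                        theta = NA_real_, theta_rand_mean = NA_real_,
                        theta_rand_sd = NA_real_, theta_norm = NA_real_,
                        theta_norm_sd = NA_real_))
    mu <- null_mean[k]; s <- null_sd[k]; th <- tp_g[k]
    data.frame(rank = ranks[i], club_size = k, theta = th,
               theta_rand_mean = mu, theta_rand_sd = s,
               theta_norm = if (mu > 0) th / mu else NA_real_,
               theta_norm_sd = if (is.finite(s) && s > 0) (th - mu) / s
                               else NA_real_)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("clubness_curve", "data.frame"),
            metric = metric, ensemble_size = ensemble$size)
}

#' @export
print.clubness_curve <- function(x, ...) {
  cat("Clubness curve (", attr(x, "metric"), "), ", nrow(x), " ranks, ",
      attr(x, "ensemble_size"), "-member null ensemble\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more ranks\n", sep = "")
  invisible(x)
}

#' @export
plot.clubness_curve <- function(x, ...) {
  ok <- is.finite(x$theta_norm)
  plot(x$rank[ok], x$theta_norm[ok], type = "l",
       xlab = "rank", ylab = expression(theta[norm]),
       main = paste("Normalized clubness:", attr(x, "metric")), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Percentage overlap between two clubs
#'
#' \code{100 * |A intersect B| / min(|A|, |B|)}: 0 when no node belongs
#' to both clubs, 100 when the clubs are identical (the \code{min}
#' denominator keeps that endpoint exact when ties make the clubs
#' unequal in size).
#'
#' @param a,b [make_club()] objects over the same node universe.
#' @return Overlap percentage in \eqn{[0, 100]}.
#' @export
club_overlap <- function(a, b) {
  if (!inherits(a, "club") || !inherits(b, "club"))
    stop("`a` and `b` must be club objects")
  if (!setequal(a$universe, b$universe))
    stop("clubs are defined over different node universes")
  if (length(a$members) == 0L || length(b$members) == 0L)
    stop("empty club")
  100 * length(intersect(a$members, b$members)) /
    min(length(a$members), length(b$members))
}

#' Percentage of communities containing a club member
#'
#' @param club A [make_club()] object.
#' @param p A [partition()] covering the club's node universe.
#' @return Percentage in \eqn{(0, 100]}.
#' @export
community_coverage <- function(club, p) {
  if (!inherits(club, "club")) stop("`club` must be a club object")
  if (!inherits(p, "partition")) stop("`p` must be a partition object")
  if (!all(club$universe %in% names(p$membership)))
    stop("partition does not cover the club's node universe")
  covered <- unique(p$membership[club$members])
  100 * length(covered) / p$n_communities
}

#' Node betweenness of club members versus non-members
#'
#' Betweenness centrality (number of shortest paths between node pairs
#' passing through a node) computed on the binarized graph, with a
#' two-sided Welch t test comparing club members against non-members
#' and a Cohen's d effect size.
#'
#' @param g A connected validated igraph object.
#' @param club A [make_club()] object.
#' @return List with \code{values} (named, all nodes), \code{members},
#'   \code{test} (htest), \code{cohens_d}, and per-group means.
#' @export
club_betweenness <- function(g, club) {
  g <- as_club_graph(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  members <- .club_members(club, g)
  b <- igraph::betweenness(binarize(g))
  inside <- names(b) %in% members
  test <- .safe_welch(b[inside], b[!inside])
  list(values = b, members = members, test = test,
       mean_club = mean(b[inside]), mean_rest = mean(b[!inside]),
       cohens_d = .cohens_d(b[inside], b[!inside]))
}

#' Edge betweenness of intra-club edges versus all other edges
#'
#' Edge betweenness (number of shortest paths traversing an edge) on
#' the binarized graph, restricted to edges with both endpoints inside
#' the club, compared against all remaining edges with a two-sided
#' Welch t test.
#'
#' @param g A connected validated igraph object.
#' @param club A [make_club()] object with at least one intra-club edge.
#' @return List with \code{values} (all edges), \code{intra} (logical
#'   mask), \code{test}, \code{cohens_d}, per-group means.
#' @export
intra_club_edge_betweenness <- function(g, club) {
  g <- as_club_graph(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  members <- .club_members(club, g)
  eb <- igraph::edge_betweenness(binarize(g))
  el <- igraph::as_edgelist(g)
  intra <- el[, 1] %in% members & el[, 2] %in% members
  if (!any(intra)) stop("club has no intra-club edges")
  test <- if (all(intra)) NULL else .safe_welch(eb[intra], eb[!intra])
  list(values = eb, intra = intra, test = test,
       mean_intra = mean(eb[intra]),
       mean_rest = if (all(intra)) NA_real_ else mean(eb[!intra]),
       cohens_d = if (all(intra)) NA_real_
                  else .cohens_d(eb[intra], eb[!intra]))
}

# Welch t test, or NULL when a group is too small or degenerate.
.safe_welch <- function(x, y) {
  tryCatch(stats::t.test(x, y), error = function(e) NULL)
}

.cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (!is.finite(sp) || sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}
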