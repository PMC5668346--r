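#' Construct a partition object
#'
#' A partition assigns every node of a graph to exactly one community,
#' with provenance (algorithm and parameters). Community indices are
#' relabeled to be contiguous \code{1..n_communities} in order of first
#' appearance.
#'
#' @param membership Integer (or factor-like) vector of community
#'   assignments, named by node label.
#' @param algorithm Name of the producing algorithm.
#' @param params Named list of parameters (cost/density, resolution,
#'   requested community count, run index, ...).
#' @return An object of class \code{partition}.
#' @export
partition <- function(membership, algorithm = "unknown", params = list()) {
  if (is.null(names(membership)) || anyDuplicated(names(membership)))
    stop("`membership` must be named by unique node labels")
  memb <- as.integer(factor(membership, levels = unique(membership)))
  names(memb) <- names(membership)
  structure(list(membership = memb,
                 n_communities = max(memb),
                 algorithm = algorithm,
                 params = params),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition (", x$algorithm, "): ", length(x$membership), " nodes in ",
      x$n_communities, " communities\n", sep = "")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# membership vector aligned to the vertex order of g, or error.
.align_partition <- function(p, g) {
  if (!inherits(p, "partition")) stop("`p` must be a partition object")
  nm <- igraph::V(g)$name
  if (!setequal(names(p$membership), nm) ||
      length(p$membership) != length(nm))
    stop("partition does not cover the graph's node set")
  unname(p$membership[nm])
}

.DC_ALGORITHMS <- c("infomap", "louvain", "louvain_resolution", "spectral",
                    "label_propagation", "edge_betweenness", "spin_glass",
                    "walktrap", "walktrap_n")

#' Detect communities with one of nine algorithms
#'
#' A uniform front end to the community-detection algorithms implemented
#' in \pkg{igraph}; none of them is re-implemented here. Available
#' algorithms:
#' \code{infomap}, \code{louvain},
#' \code{louvain_resolution} (modularity maximization with resolution
#' parameter \code{gamma}; an approximation of stability-based
#' multi-scale Louvain through its resolution interface),
#' \code{spectral} (leading eigenvector), \code{label_propagation},
#' \code{edge_betweenness} (run on a binarized copy of the graph,
#' because weighted shortest paths would treat strong edges as long
#' distances), \code{spin_glass}, \code{walktrap}, and
#' \code{walktrap_n} (Walktrap with its dendrogram cut to the requested
#' community count, or to as many communities as the recorded merges
#' allow, whichever comes first).
#'
#' All algorithms except \code{edge_betweenness} see the edge weights.
#' Stochastic algorithms are deterministic under a fixed \code{seed}.
#'
#' @param g A validated igraph object; connected for path-based
#'   algorithms (\code{edge_betweenness}, \code{spin_glass}).
#' @param algorithm Algorithm name (see above).
#' @param params Named list: \code{gamma} (resolution, default 1;
#'   \code{louvain_resolution}), \code{n_communities}
#'   (\code{walktrap_n}), \code{steps} (walktrap random-walk length,
#'   default 4), \code{trials} (infomap, default 10), \code{spins}
#'   (spin_glass, default 25).
#' @param seed Optional integer seed.
#' @return A [partition()] object.
#' @export
detect_communities <- function(g, algorithm, params = list(), seed = NULL) {
  g <- as_club_graph(g)
  if (!algorithm %in% .DC_ALGORITHMS)
    stop("unknown algorithm '", algorithm, "'; available: ",
         paste(.DC_ALGORITHMS, collapse = ", "))
  comm <- with_seed_opt(seed, switch(
    algorithm,
    infomap = igraph::cluster_infomap(
      g, nb.trials = params$trials %||% 10L),
    louvain = igraph::cluster_louvain(g),
    louvain_resolution = igraph::cluster_louvain(
      g, resolution = params$gamma %||% 1),
    spectral = igraph::cluster_leading_eigen(g),
    label_propagation = igraph::cluster_label_prop(g),
    edge_betweenness = suppressWarnings(   # igraph notes the dendrogram
      igraph::cluster_edge_betweenness(    # cut maximizing modularity
        binarize(g), weights = NULL)),
    spin_glass = {
      if (!igraph::is_connected(g))
        stop("spin_glass requires a connected graph")
      igraph::cluster_spinglass(g, spins = params$spins %||% 25L)
    },
    walktrap = igraph::cluster_walktrap(g, steps = params$steps %||% 4L),
    walktrap_n = .walktrap_n(g, params)
  ))
  memb <- if (inherits(comm, "communities")) igraph::membership(comm) else comm
  partition(setNames(as.integer(memb), igraph::V(g)$name),
            algorithm = algorithm, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Walktrap cut to a requested number of communities. Merges are replayed
# until that count is reached or the recorded merges run out, whichever
# happens first (fewer merges than needed leaves more communities).
.walktrap_n <- function(g, params) {
  n_req <- params$n_communities
  if (is.null(n_req)) stop("walktrap_n requires params$n_communities")
  n <- igraph::vcount(g)
  if (n_req > n) stop("requested community count exceeds node count")
  wt <- igraph::cluster_walktrap(g, steps = params$steps %||% 4L)
  n_merges <- nrow(wt$merges)
  achievable <- max(n_req, n - n_merges)
  igraph::cut_at(wt, no = achievable)
}

#' Apply a community-detection algorithm over a parameter grid
#'
#' Runs [detect_communities()] once per grid point. A grid point with a
#' \code{density} (or \code{cost}) entry first thresholds the graph at
#' that cost via [threshold_graph()] -- the usual density sweep for
#' weighted functional networks. A \code{run} entry simply distinguishes
#' repeated seeded runs on the same (e.g. structural, unthresholded)
#' graph. Remaining entries are passed through as algorithm parameters.
#' Errors at individual grid points are captured and returned in place
#' of a partition, without aborting the sweep.
#'
#' @param g A validated igraph object.
#' @param algorithm Algorithm name, as in [detect_communities()].
#' @param grid Non-empty list of named parameter lists.
#' @param seed Optional master seed; each grid point receives its own
#'   derived seed so sweeps are reproducible.
#' @return A list, one element per grid point: a [partition()] (with the
#'   grid point recorded in \code{params}) or a \code{condition} object
#'   if that point failed.
#' @export
sweep_partitions <- function(g, algorithm, grid, seed = NULL) {
  g <- as_club_graph(g)
  if (!is.list(grid) || length(grid) == 0L) stop("`grid` must be non-empty")
  seeds <- child_seeds(seed, length(grid))
  Map(function(point, s) {
    tryCatch({
      stopifnot(is.list(point))
      gg <- g
      cost <- point$density %||% point$cost
      if (!is.null(cost)) gg <- threshold_graph(g, cost)
      pars <- point[setdiff(names(point), c("density", "cost", "run"))]
      p <- detect_communities(gg, algorithm, params = pars, seed = s)
      p$params <- point
      p
    }, error = function(e) e)
  }, grid, seeds)
}
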