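#' Validate and normalize a graph for club analysis
#'
#' Checks that \code{g} is an undirected simple \pkg{igraph} graph with at
#' least two nodes and strictly positive edge weights, assigns unit
#' weights if the \code{weight} attribute is absent (binary graph), and
#' assigns character vertex names if absent.
#'
#' @param g An igraph object.
#' @return The normalized igraph object.
#' @export
as_club_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object")
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (igraph::vcount(g) < 2L) stop("graph must have at least 2 nodes")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    stop("graph must be simple (no self-loops or multi-edges)")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (anyDuplicated(igraph::V(g)$name)) stop("node labels must be unique")
  if (is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  } else if (igraph::ecount(g) > 0 && any(igraph::E(g)$weight <= 0)) {
    stop("all edge weights must be > 0 (zero-weight pairs are absent edges)")
  }
  g
}

#' Binarize a graph
#'
#' Sets every edge weight to 1. Shortest-path based quantities
#' (efficiency, betweenness, edge betweenness) are computed on binarized
#' graphs throughout the package: the binary presence of a connection is
#' what matters for path traversal, not its weight.
#'
#' @param g An igraph object.
#' @return The graph with all weights equal to 1.
#' @export
binarize <- function(g) {
  g <- as_club_graph(g)
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

#' Load an undirected weighted graph from a file
#'
#' Supported formats:
#' \describe{
#'   \item{\code{edgelist}}{TSV with columns \code{node_a}, \code{node_b}
#'     and optionally \code{weight} (defaulting to 1). A header row with
#'     those names is recognized and skipped; lines starting with
#'     \code{#} are comments. A node pair listed twice with conflicting
#'     weights is an error.}
#'   \item{\code{matrix}}{CSV holding a square symmetric adjacency or
#'     correlation matrix (symmetry tolerance 1e-8), with optional
#'     header row / first-column labels. Off-diagonal non-zero entries
#'     become edges; the diagonal is ignored.}
#'   \item{\code{graphml}}{GraphML, for round-tripping with external
#'     tools.}
#' }
#'
#' Correlation-derived matrices may contain negative entries; these are
#' not meaningful as connection strengths here, so they are either
#' dropped (no edge for that pair) or rejected, per
#' \code{negative_policy}.
#'
#' @param path Path to the input file.
#' @param format One of \code{"edgelist"}, \code{"matrix"},
#'   \code{"graphml"}. Default guesses from the file extension.
#' @param negative_policy \code{"drop"} (default) or \code{"error"}.
#' @return A validated igraph object (see [as_club_graph()]).
#' @export
load_graph <- function(path,
                       format = c("auto", "edgelist", "matrix", "graphml"),
                       negative_policy = c("drop", "error")) {
  format <- match.arg(format)
  negative_policy <- match.arg(negative_policy)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     tsv = "edgelist", txt = "edgelist", edgelist = "edgelist",
                     csv = "matrix", graphml = "graphml",
                     stop("cannot guess format from extension '", ext,
                          "'; pass `format` explicitly"))
  }
  g <- switch(format,
              edgelist = .load_edgelist(path, negative_policy),
              matrix = .load_matrix(path, negative_policy),
              graphml = .load_graphml(path, negative_policy))
  as_club_graph(g)
}

.apply_negative_policy <- function(from, to, w, negative_policy) {
  neg <- w < 0
  if (any(neg)) {
    if (negative_policy == "error")
      stop("negative edge weights present and negative_policy = 'error'")
    from <- from[!neg]; to <- to[!neg]; w <- w[!neg]
  }
  list(from = from, to = to, w = w)
}

.load_edgelist <- function(path, negative_policy) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, header = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  if (identical(tolower(df[1, 1]), "node_a") &&
      identical(tolower(df[1, 2]), "node_b"))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0L) stop("edge list contains no edges")
  from <- df[[1]]; to <- df[[2]]
  w <- if (ncol(df) >= 3L) as.numeric(df[[3]]) else rep(1, nrow(df))
  if (anyNA(w)) stop("non-numeric weight in edge list")
  if (any(from == to)) stop("self-loops are not allowed")
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  if (anyDuplicated(key)) {
    groups <- split(w, key)
    conflicting <- vapply(groups, function(x) length(unique(x)) > 1L,
                          logical(1))
    if (any(conflicting))
      stop("duplicate node pair with conflicting weights in edge list")
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  }
  parts <- .apply_negative_policy(from, to, w, negative_policy)
  zero <- parts$w == 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = parts$from[!zero], to = parts$to[!zero],
               weight = parts$w[!zero]),
    directed = FALSE,
    vertices = unique(c(from, to)))
  g
}

.load_matrix <- function(path, negative_policy) {
  raw <- read.table(path, sep = ",", stringsAsFactors = FALSE,
                    header = FALSE, colClasses = "character",
                    comment.char = "#")
  has_header <- is.na(suppressWarnings(as.numeric(raw[1, ncol(raw)])))
  if (has_header) {
    labels <- as.character(raw[1, -1])
    raw <- raw[-1, -1, drop = FALSE]
  } else if (nrow(raw) >= 2 &&
             is.na(suppressWarnings(as.numeric(raw[2, 1])))) {
    # row labels only
    labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  } else {
    labels <- as.character(seq_len(nrow(raw)))
  }
  A <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  if (anyNA(A)) stop("matrix contains non-numeric entries")
  if (nrow(A) != ncol(A)) stop("matrix input must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("matrix input must be symmetric")
  n <- nrow(A)
  if (n < 2L) stop("graph must have at least 2 nodes")
  diag(A) <- 0
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  parts <- .apply_negative_policy(labels[idx[, 1]], labels[idx[, 2]],
                                  A[idx], negative_policy)
  igraph::graph_from_data_frame(
    data.frame(from = parts$from, to = parts$to, weight = parts$w),
    directed = FALSE, vertices = labels)
}

.load_graphml <- function(path, negative_policy) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) stop("GraphML input must be undirected")
  if (!is.null(igraph::E(g)$weight)) {
    w <- igraph::E(g)$weight
    neg <- w < 0
    if (any(neg)) {
      if (negative_policy == "error")
        stop("negative edge weights present and negative_policy = 'error'")
      g <- igraph::delete_edges(g, which(neg))
    }
    g <- igraph::delete_edges(g, which(igraph::E(g)$weight == 0))
  }
  g
}

#' Write a graph as an edge-list TSV
#'
#' Columns \code{node_a}, \code{node_b}, \code{weight}; the format
#' [load_graph()] reads back.
#'
#' @param g An igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  g <- as_club_graph(g)
  el <- igraph::as_edgelist(g)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = igraph::E(g)$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Threshold a weighted graph at a target edge cost
#'
#' Retains the top-weighted edges up to a budget of
#' \code{floor(cost * n * (n - 1) / 2)} edges, while always keeping every
#' edge of the maximum spanning tree so the result stays connected (the
#' MST edges count toward the budget; if the budget is below \code{n - 1}
#' the result still contains all \code{n - 1} MST edges). Ties in edge
#' weight at the cutoff are broken by the lexicographic order of the
#' node-label pairs, so thresholding is deterministic.
#'
#' @param g A connected weighted igraph object.
#' @param cost Fraction of possible edges to retain, in (0, 1].
#' @return The thresholded graph.
#' @export
threshold_graph <- function(g, cost) {
  g <- as_club_graph(g)
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1)
    stop("`cost` must be a single number in (0, 1]")
  if (!igraph::is_connected(g))
    stop("graph must be connected (maximum spanning tree undefined otherwise)")
  n <- igraph::vcount(g)
  budget <- floor(cost * n * (n - 1) / 2)
  if (budget >= igraph::ecount(g)) return(g)
  # maximum spanning tree = minimum spanning tree on negated weights
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  mst_ids <- igraph::get_edge_ids(g, t(igraph::as_edgelist(mst, names = FALSE)))
  in_mst <- seq_len(igraph::ecount(g)) %in% mst_ids
  extra <- budget - sum(in_mst)
  keep <- in_mst
  if (extra > 0) {
    el <- igraph::as_edgelist(g)
    pair_a <- pmin(el[, 1], el[, 2])
    pair_b <- pmax(el[, 1], el[, 2])
    cand <- which(!in_mst)
    ord <- cand[order(-igraph::E(g)$weight[cand], pair_a[cand], pair_b[cand])]
    keep[utils::head(ord, extra)] <- TRUE
  }
  igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
}

#' Degree-preserving randomized null ensemble
#'
#' Generates \code{size} randomized versions of \code{g} by iterated
#' double-edge swaps (at least \code{10 * ecount(g)} swap attempts per
#' member), so every member has exactly the source's degree sequence,
#' node set and edge count. Edge weights travel with their edges through
#' the swaps, preserving the weight multiset. In
#' \code{mode = "weights"}, weights are additionally shuffled among
#' edges whose unordered pair of endpoint degrees matches, which
#' randomizes the weight-to-edge assignment while keeping the relation
#' between weights and endpoint degrees intact.
#'
#' If no degree-preserving swap is possible (e.g. a star graph), members
#' equal the source topology and a warning is issued.
#'
#' @param g A validated igraph object with at least one edge.
#' @param size Number of randomized graphs (default 1000).
#' @param mode \code{"topology"} (default) or \code{"weights"}.
#' @param seed Optional integer seed; the whole ensemble is a
#'   deterministic function of it.
#' @return An object of class \code{null_ensemble}: a list with elements
#'   \code{source}, \code{graphs}, \code{size}, \code{mode}, \code{seed}.
#' @export
randomize <- function(g, size = 1000, mode = c("topology", "weights"),
                      seed = NULL) {
  g <- as_club_graph(g)
  mode <- match.arg(mode)
  m <- igraph::ecount(g)
  if (m < 1L) stop("graph must have at least one edge")
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  n <- igraph::vcount(g)
  graphs <- with_seed_opt(seed, {
    lapply(seq_len(size), function(i) {
      el_r <- double_edge_swap(n, el, 10L * m)
      r <- igraph::make_empty_graph(n, directed = FALSE)
      igraph::V(r)$name <- igraph::V(g)$name
      r <- igraph::add_edges(r, t(el_r), weight = w)
      if (mode == "weights") r <- .shuffle_weights_by_degree(r)
      r
    })
  })
  src_key <- .edge_key(g)
  if (size > 0 && all(vapply(graphs, function(x)
        identical(.edge_key(x), src_key), logical(1))))
    warning("no degree-preserving swap changed the topology; ",
            "ensemble members equal the source graph")
  structure(list(source = g, graphs = graphs, size = size,
                 mode = mode, seed = seed),
            class = "null_ensemble")
}

.edge_key <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  sort(key)
}

# Permute edge weights within groups of edges sharing the same unordered
# endpoint-degree pair. Uses the caller's RNG stream.
.shuffle_weights_by_degree <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  d1 <- deg[el[, 1]]; d2 <- deg[el[, 2]]
  grp <- paste(pmin(d1, d2), pmax(d1, d2))
  w <- igraph::E(g)$weight
  for (ids in split(seq_along(w), grp)) {
    if (length(ids) > 1L) w[ids] <- w[sample(ids)]
  }
  igraph::E(g)$weight <- w
  g
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Degree-preserving null ensemble\n")
  cat("  source: ", igraph::vcount(x$source), " nodes, ",
      igraph::ecount(x$source), " edges\n", sep = "")
  cat("  members:", x$size, " mode:", x$mode, "\n")
  invisible(x)
}
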