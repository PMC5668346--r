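# Independent oracles, deliberately written without reusing package
# internals or the code paths they check.

# Modularity by literal double summation over ordered pairs i != j.
brute_modularity <- function(A, memb, gamma = 1) {
  s <- sum(A) / 2
  k <- rowSums(A)
  n <- nrow(A)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || memb[i] != memb[j]) next
    total <- total + A[i, j] - gamma * k[i] * k[j] / (2 * s)
  }
  as.numeric(total / (2 * s))
}

# All-pairs path sum by hand-rolled breadth-first search.
bfs_path_sum <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(i)
    c(el[el[, 1] == i, 2], el[el[, 2] == i, 1]))
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (v in adj[[u]]) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        nxt <- c(nxt, v)
      }
      frontier <- nxt
    }
    if (anyNA(dist)) stop("disconnected")
    total <- total + sum(dist)
  }
  total / 2
}

# Competition rank by counting strictly smaller values.
counting_rank <- function(x) vapply(x, function(v) 1L + sum(x < v),
                                    integer(1))

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# Maximum spanning tree by enumerating every spanning tree (tiny n).
brute_max_spanning_tree <- function(g) {
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  best <- NULL; best_w <- -Inf
  for (ids in utils::combn(m, n - 1, simplify = FALSE)) {
    sub <- igraph::subgraph_from_edges(g, ids, delete.vertices = FALSE)
    if (!igraph::is_connected(sub)) next
    w <- sum(igraph::E(sub)$weight)
    if (w > best_w) { best_w <- w; best <- ids }
  }
  list(edge_ids = best, weight = best_w)
}
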