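test_that("club sizing follows the percentile and rank rules", {
  withr::with_seed(1, {
    v264 <- setNames(sample(seq_len(1000), 264), paste0("n", 1:264))
  })
  club <- make_club(v264, percentile = 80)
  expect_length(club$members, 53)

  # rank form: members have value >= the (n - r)-th highest
  withr::with_seed(2, {
    v100 <- setNames(sample(seq_len(500), 100), paste0("n", 1:100))
  })
  c85 <- make_club(v100, rank = 85)
  expect_length(c85$members, 15)
  expect_equal(c85$threshold_value,
               unname(sort(v100, decreasing = TRUE)[15]))
  expect_true(all(v100[c85$members] >= c85$threshold_value))

  # ties spanning the cutoff are all included
  vt <- setNames(c(10, 9, 8, 8, 8, 7, 6, 5, 4, 3), paste0("n", 1:10))
  ct <- make_club(vt, percentile = 70)     # nominal 3, but three 8s tie
  expect_length(ct$members, 5)

  expect_error(make_club(setNames(rep(1, 5), letters[1:5]),
                         percentile = 80), "identical")
})

test_that("clubness is intra-club weight over possible pairs", {
  g <- two_cliques()
  clique_club <- structure(list(members = as.character(1:5),
                                metric = "strength",
                                threshold_value = 0, nominal_size = 5L,
                                universe = as.character(1:10)),
                           class = "club")
  expect_equal(clubness(g, clique_club), 1)    # binary clique

  # 3 nodes, two unit edges present, third pair absent -> 2/3
  gp <- as_club_graph(igraph::make_graph(~ a - b, b - c, c - d))
  path_club <- structure(list(members = c("a", "b", "c"),
                              metric = "strength", threshold_value = 0,
                              nominal_size = 3L,
                              universe = c("a", "b", "c", "d")),
                         class = "club")
  expect_equal(clubness(gp, path_club), 2 / 3)

  # no intra-club edges -> 0
  empty_club <- structure(list(members = c("a", "c"),
                               metric = "strength", threshold_value = 0,
                               nominal_size = 2L,
                               universe = c("a", "b", "c", "d")),
                          class = "club")
  expect_equal(clubness(gp, empty_club), 0)
  single <- structure(list(members = "a", metric = "strength",
                           threshold_value = 0, nominal_size = 1L,
                           universe = c("a", "b", "c", "d")),
                      class = "club")
  expect_error(clubness(gp, single), "at least 2")
})

test_that("whole-set clubness equals density on binary graphs", {
  g <- er_graph(30, 0.2, seed = 3)
  all_club <- structure(list(members = igraph::V(g)$name,
                             metric = "strength", threshold_value = 0,
                             nominal_size = 30L,
                             universe = igraph::V(g)$name),
                        class = "club")
  expect_equal(clubness(g, all_club),
               igraph::ecount(g) / (30 * 29 / 2))
})

test_that("adding an intra-club edge strictly increases clubness", {
  withr::with_seed(8, {
    for (i in 1:10) {
      g <- er_graph(20, 0.3)
      members <- sample(igraph::V(g)$name, 6)
      club <- structure(list(members = members, metric = "m",
                             threshold_value = 0, nominal_size = 6L,
                             universe = igraph::V(g)$name),
                        class = "club")
      pairs <- t(utils::combn(members, 2))
      absent <- pairs[igraph::get_edge_ids(g, t(pairs)) == 0, ,
                      drop = FALSE]
      if (nrow(absent) == 0) next
      theta0 <- clubness(g, club)
      g2 <- igraph::add_edges(g, absent[1, ], weight = 1)
      expect_gt(clubness(g2, club), theta0)
    }
  })
})

test_that("self-normalization yields exactly 1", {
  g <- bridge_fixture()$graph
  pc <- participation_coefficient(g, bridge_fixture()$partition)
  club <- make_club(pc, percentile = 80, metric = "participation")
  self_ens <- structure(list(source = g, graphs = list(g), size = 1L,
                             mode = "topology", seed = NULL),
                        class = "null_ensemble")
  expect_equal(normalized_clubness(g, club, self_ens)$theta_norm, 1)
})

test_that("theta_norm exceeds 1 exactly when theta beats the null mean", {
  g <- bridge_fixture()$graph
  pc <- participation_coefficient(g, bridge_fixture()$partition)
  club <- make_club(pc, percentile = 80, metric = "participation")
  ens <- randomize(g, 100, seed = 5)
  nc <- normalized_clubness(g, club, ens)
  expect_equal(nc$theta_norm > 1, nc$theta > nc$theta_rand_mean)
})

test_that("clubness curves cover the requested ranks and share the null", {
  pp <- bridge_fixture()
  g <- pp$graph
  pc <- participation_coefficient(g, pp$partition)
  ens <- cached("bridge_ens", randomize(g, 200, seed = 5))
  ranks <- c(10, 30, 50, 60, 63)
  curve <- clubness_curve(g, pc, ens, ranks = ranks,
                          metric = "participation")
  expect_equal(nrow(curve), length(ranks))
  expect_equal(curve$rank, ranks)
  n <- igraph::vcount(g)
  expect_true(all(curve$club_size >= n - ranks, na.rm = TRUE))
  ok <- is.finite(curve$theta_norm)
  expect_equal(curve$theta_norm[ok],
               (curve$theta / curve$theta_rand_mean)[ok])
})

test_that("the designed diverse club out-clubs the rich club at top ranks", {
  pp <- bridge_fixture()
  g <- pp$graph
  p <- detect_communities(g, "infomap", seed = 1)
  pc <- participation_coefficient(g, p)
  st <- node_strength(g)
  ens <- cached("bridge_ens", randomize(g, 200, seed = 5))
  cd <- clubness_curve(g, pc, ens, metric = "participation")
  cr <- clubness_curve(g, st, ens, metric = "strength")
  top_d <- !is.na(cd$club_size) & cd$club_size <= 14
  top_r <- !is.na(cr$club_size) & cr$club_size <= 14
  expect_gt(mean(cd$theta_norm[top_d], na.rm = TRUE),
            mean(cr$theta_norm[top_r], na.rm = TRUE))
})

test_that("clubness rises with the club threshold on club-bearing fixtures", {
  pp <- bridge_fixture()
  g <- pp$graph
  p <- detect_communities(g, "infomap", seed = 1)
  pc <- participation_coefficient(g, p)
  out <- t(vapply(seq(30, 90, by = 10), function(pct) {
    club <- make_club(pc, percentile = pct, metric = "participation")
    c(threshold = club$threshold_value, theta = clubness(g, club))
  }, numeric(2)))
  expect_gt(stats::cor(out[, "threshold"], out[, "theta"],
                       method = "spearman"), 0)
})

test_that("normalized clubness agrees across two independent null seeds", {
  pp <- bridge_fixture()
  g <- pp$graph
  pc <- participation_coefficient(g, pp$partition)
  club <- make_club(pc, percentile = 80, metric = "participation")
  n1 <- normalized_clubness(g, club, randomize(g, 300, seed = 101))
  n2 <- normalized_clubness(g, club, randomize(g, 300, seed = 202))
  se <- function(x) (x$theta_rand_sd / sqrt(300)) / x$theta_rand_mean
  expect_lt(abs(n1$theta_norm - n2$theta_norm),
            3 * sqrt(se(n1)^2 + se(n2)^2))
})

test_that("club overlap endpoints and partial overlap are exact", {
  u <- paste0("n", 1:100)
  mk <- function(members) structure(
    list(members = members, metric = "m", threshold_value = 0,
         nominal_size = length(members), universe = u), class = "club")
  a <- mk(u[1:53]); b <- mk(u[1:53])
  expect_equal(club_overlap(a, b), 100)
  expect_equal(club_overlap(mk(u[1:20]), mk(u[21:40])), 0)
  expect_equal(club_overlap(mk(u[1:53]), mk(u[42:94])), 100 * 12 / 53)
})

test_that("community coverage counts communities holding a member", {
  u <- paste0("n", 1:20)
  p <- partition(setNames(rep(1:5, each = 4), u))
  mk <- function(members) structure(
    list(members = members, metric = "m", threshold_value = 0,
         nominal_size = length(members), universe = u), class = "club")
  expect_equal(community_coverage(mk(u[c(1, 5, 9, 13, 17)]), p), 100)
  expect_equal(community_coverage(mk(u[c(1, 5, 9)]), p), 60)
  expect_gte(community_coverage(mk(u[1]), p), 100 / 5)
})

test_that("betweenness comparisons behave on canonical graphs", {
  star <- as_club_graph(igraph::make_star(7, mode = "undirected"))
  club <- structure(list(members = "1", metric = "m", threshold_value = 0,
                         nominal_size = 1L,
                         universe = igraph::V(star)$name),
                    class = "club")
  res <- club_betweenness(star, club)
  expect_equal(unname(res$values["1"]), choose(6, 2))  # all pairs via hub
  expect_true(all(res$values[-1] == 0))                # leaves

  gp <- as_club_graph(igraph::make_graph(~ a - b, b - c))
  resp <- club_betweenness(gp, structure(
    list(members = "b", metric = "m", threshold_value = 0,
         nominal_size = 1L, universe = c("a", "b", "c")), class = "club"))
  expect_equal(unname(resp$values["b"]), 1)
})

test_that("the bridge edge between cliques has the top edge betweenness", {
  g <- two_cliques()
  club <- structure(list(members = c("5", "6"), metric = "m",
                         threshold_value = 0, nominal_size = 2L,
                         universe = as.character(1:10)), class = "club")
  res <- intra_club_edge_betweenness(g, club)
  expect_equal(sum(res$intra), 1)
  expect_equal(res$values[res$intra], max(res$values))
  expect_true(all(res$values[!res$intra] < res$values[res$intra]))
  # Welch comparison reports the intra edge far above the rest
  expect_gt(res$mean_intra, res$mean_rest)

  no_intra <- structure(list(members = c("1", "6"), metric = "m",
                             threshold_value = 0, nominal_size = 2L,
                             universe = as.character(1:10)),
                        class = "club")
  expect_error(intra_club_edge_betweenness(g, no_intra), "no intra-club")
})

test_that("edge betweenness sums to total pair distance on trees", {
  # on a tree shortest paths are unique, so summing edge betweenness
  # over all edges must reproduce the all-pairs path sum
  withr::with_seed(4, {
    for (i in 1:5) {
      tree <- as_club_graph(igraph::sample_tree(12))
      club <- structure(list(members = igraph::V(tree)$name,
                             metric = "m", threshold_value = 0,
                             nominal_size = 12L,
                             universe = igraph::V(tree)$name),
                        class = "club")
      res <- intra_club_edge_betweenness(tree, club)
      expect_true(all(res$intra))
      expect_equal(sum(res$values), path_sum(tree))
    }
  })
})
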