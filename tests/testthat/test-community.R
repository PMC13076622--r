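mk_graph <- function(edges, nodes = sort(unique(c(edges$u, edges$v)))) {
  structure(list(edges = edges, nodes = nodes, alpha = 2, beta = 0,
                 feature_subset = "f2"),
            class = "tree_graph")
}

test_that("modularity matches hand-evaluated cases", {
  tri <- mk_graph(tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"),
                                 weight = 1))
  one <- stats::setNames(c(1, 1, 1), c("a", "b", "c"))
  expect_equal(graph_modularity(tri, one), 0)
  singletons <- stats::setNames(1:3, c("a", "b", "c"))
  expect_equal(graph_modularity(tri, singletons), -1 / 3)

  # two disconnected 3-cliques split correctly: e_c = 1/2, a_c = 1/2 each
  cl <- tibble::tibble(
    u = c("a", "a", "b", "x", "x", "y"),
    v = c("b", "c", "c", "y", "z", "z"), weight = 1)
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2),
                          c("a", "b", "c", "x", "y", "z"))
  expect_equal(graph_modularity(mk_graph(cl), memb), 0.5)

  empty <- mk_graph(tibble::tibble(u = character(), v = character(),
                                   weight = double()), nodes = c("a", "b"))
  expect_error(graph_modularity(empty, stats::setNames(1:2, c("a", "b"))),
               class = "crowncluster_empty_graph")
})

test_that("greedy detection recovers two cliques joined by a weak edge", {
  # exhaustive search over all partitions of 8 nodes confirms the optimum
  nodes <- letters[1:8]
  cl1 <- t(combn(letters[1:4], 2))
  cl2 <- t(combn(letters[5:8], 2))
  edges <- tibble::tibble(u = c(cl1[, 1], cl2[, 1], "d"),
                          v = c(cl1[, 2], cl2[, 2], "e"),
                          weight = c(rep(1, 12), 0.1))
  g <- mk_graph(edges)
  comm <- detect_communities(g)
  expect_equal(comm$n_communities, 2L)
  split <- split(comm$assignment$tree_id, comm$assignment$community)
  expect_setequal(split[[1]], letters[1:4])
  expect_setequal(split[[2]], letters[5:8])
  best <- oracle_best_modularity(nodes, edges)
  expect_equal(comm$modularity, best, tolerance = 1e-12)
})

test_that("greedy Q is bounded by the exhaustive optimum on random small graphs", {
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(4:7, 1)
    nodes <- letters[seq_len(n)]
    all_pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(all_pairs)) < 0.6
    if (sum(keep) < 2) keep[1:2] <- TRUE
    edges <- tibble::tibble(u = all_pairs[keep, 1], v = all_pairs[keep, 2],
                            weight = round(runif(sum(keep), 0.05, 1), 3))
    g <- mk_graph(edges, nodes = nodes)
    comm <- suppressWarnings(detect_communities(g))
    best <- oracle_best_modularity(nodes, edges)
    expect_lte(comm$modularity, best + 1e-12)
    singles <- stats::setNames(seq_len(n), nodes)
    expect_gte(comm$modularity,
               oracle_modularity(edges, singles) - 1e-12)
    # reported Q equals an independent recomputation
    memb <- stats::setNames(comm$assignment$community,
                            comm$assignment$tree_id)
    expect_equal(comm$modularity, oracle_modularity(edges, memb),
                 tolerance = 1e-9)
  }
})

test_that("communities never span disconnected components and runs repeat exactly", {
  cl <- tibble::tibble(
    u = c("a", "a", "b", "x", "x", "y"),
    v = c("b", "c", "c", "y", "z", "z"), weight = c(1, 1, 1, 2, 2, 2))
  g <- mk_graph(cl)
  c1 <- detect_communities(g)
  c2 <- detect_communities(g)
  expect_identical(c1, c2)
  memb <- stats::setNames(c1$assignment$community, c1$assignment$tree_id)
  expect_false(any(memb[c("a", "b", "c")] %in% memb[c("x", "y", "z")]))
})

test_that("edgeless graphs give singleton communities with a warning", {
  g <- mk_graph(tibble::tibble(u = character(), v = character(),
                               weight = double()), nodes = c("a", "b", "c"))
  expect_warning(comm <- detect_communities(g), "singleton")
  expect_equal(comm$n_communities, 3L)
  expect_equal(comm$modularity, 0)
  expect_equal(comm$assignment$community, 0:2)
})

test_that("isolated nodes stay singletons alongside detected communities", {
  cl <- tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"), weight = 1)
  g <- mk_graph(cl, nodes = c("a", "b", "c", "lonely"))
  comm <- detect_communities(g)
  asg <- comm$assignment
  expect_equal(sum(asg$community == asg$community[asg$tree_id == "lonely"]),
               1L)
})

test_that("greedy agreement with the igraph reference on a generated forest", {
  skip_if_not_installed("igraph")
  forest <- small_forest(seed = 33L, n = 4L)
  feats <- extract_forest_features(forest)
  g <- build_tree_graph(feats)
  ours <- detect_communities(g)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  ref <- igraph::cluster_fast_greedy(ig, weights = igraph::E(ig)$weight)
  ref_memb <- stats::setNames(igraph::membership(ref),
                              igraph::V(ig)$name)
  agg <- partition_agreement(
    stats::setNames(ours$assignment$community, ours$assignment$tree_id),
    ref_memb)
  # same optimisation family; tie-breaking may differ marginally
  expect_gte(agg$adjusted_rand_index, 0.9)
  expect_equal(ours$modularity,
               igraph::modularity(ig, ref_memb[g$nodes] + 1,
                                  weights = igraph::E(ig)$weight),
               tolerance = 0.02)
})

test_that("tidy and glance expose the assignment and the fit summary", {
  cl <- tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"), weight = 1)
  comm <- detect_communities(mk_graph(cl))
  td <- tidy(comm)
  expect_identical(names(td), c("tree_id", "community"))
  expect_equal(nrow(td), 3L)
  gl <- glance(comm)
  expect_identical(names(gl),
                   c("n_trees", "n_communities", "modularity", "method"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(comm, f)
  expect_equal(as.data.frame(read_partition_csv(f)), as.data.frame(td))
})
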