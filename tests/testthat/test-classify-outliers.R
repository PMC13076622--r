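fixture_partition <- function() {
  asg <- tibble::tibble(
    tree_id = sprintf("t%02d", 1:12),
    community = rep(0:2, each = 4L))
  truth <- stats::setNames(
    c(rep("ash", 4), c("oak", "oak", "oak", "ash"), rep("fir", 4)),
    asg$tree_id)
  list(assignment = asg, truth = truth)
}

test_that("majority vote labels communities by plurality with lexicographic ties", {
  fx <- fixture_partition()
  res <- majority_vote(fx$assignment, fx$truth, k_per_community = 4L,
                       seed = 1L)
  expect_identical(res$community_labels$species, c("ash", "oak", "fir"))
  # k >= community size: sampling-free, all trees predicted
  expect_identical(
    res$predicted$predicted_species,
    unname(c(rep("ash", 4), c("oak", "oak", "oak", "ash"), rep("fir", 4))))

  # sampled trees keep their ground truth even against the community label
  expect_identical(res$predicted$predicted_species[8L], "ash")

  # tie between two species resolves to the lexicographically smallest
  tie <- tibble::tibble(tree_id = c("a", "b"), community = c(0L, 0L))
  tr <- c(a = "oak", b = "ash")
  res_tie <- majority_vote(tie, tr, k_per_community = 2L, seed = 1L)
  expect_identical(res_tie$community_labels$species, "ash")

  # community without any labels errors, naming the community
  expect_error(
    majority_vote(fx$assignment, fx$truth[1:8], k_per_community = 1L,
                  seed = 1L),
    "community 2", class = "crowncluster_no_labels")
})

test_that("vote sampling is reproducible and k-capped", {
  fx <- fixture_partition()
  r1 <- majority_vote(fx$assignment, fx$truth, k_per_community = 2L, seed = 9L)
  r2 <- majority_vote(fx$assignment, fx$truth, k_per_community = 2L, seed = 9L)
  expect_identical(r1, r2)
  expect_true(all(r1$community_labels$n_sampled == 2L))
})

test_that("vote accuracy trends upward with k on a fixed mixed partition", {
  set.seed(11)
  n <- 60L
  asg <- tibble::tibble(tree_id = sprintf("t%03d", 1:n),
                        community = rep(0:2, each = 20L))
  truth <- stats::setNames(
    c(sample(c(rep("a", 14), rep("b", 6))),
      sample(c(rep("b", 12), rep("c", 8))),
      sample(c(rep("c", 16), rep("a", 4)))),
    asg$tree_id)
  acc_at <- function(k) {
    mean(vapply(1:100, function(s) {
      res <- majority_vote(asg, truth, k_per_community = k, seed = s)
      mean(res$predicted$predicted_species ==
             truth[res$predicted$tree_id])
    }, 0))
  }
  a1 <- acc_at(1L)
  a5 <- acc_at(5L)
  a15 <- acc_at(15L)
  expect_gte(a5, a1 - 0.02)
  expect_gte(a15, a5 - 0.02)
  expect_gt(a15, a1)
})

test_that("perfectly pure partitions classify everything from one label each", {
  forest <- small_forest(seed = 14L, n = 4L)
  run <- run_pipeline(forest, vote_k = 1L)
  expect_equal(run$agreement$adjusted_rand_index, 1)
  expect_equal(run$classification$accuracy, 1)
})

test_that("mean-weight ranks follow the definition and flag injected outliers", {
  forest <- small_forest(seed = 15L, n = 4L)
  feats <- extract_forest_features(forest)

  # candidate identical to an existing tree ties its mean weight
  twin <- feats[1L, ]
  twin$tree_id <- "zz_twin"
  feats2 <- dplyr::bind_rows(feats, twin)
  r_twin <- outlier_mean_weight_rank(feats2, "zz_twin")
  r_orig <- outlier_mean_weight_rank(feats2, feats$tree_id[1L])
  expect_equal(r_twin$mean_weight, r_orig$mean_weight, tolerance = 1e-12)
  expect_equal(r_twin$rank, r_orig$rank)

  # a radically different tree lands at rank 1
  alien <- species_profile("alien", c(6, 0.2, 5, 0.2, 6, 0.1), c(40, 45),
                           trunk_fraction = 0.02, density = 2,
                           asymmetry = 1.5, noise_sd = 0.8)
  atree <- sample_tree(alien, seed = 1L, tree_id = "zz_alien")
  af <- extract_features(atree)
  arow <- dplyr::bind_cols(
    tibble::tibble(tree_id = "zz_alien", species = "alien"),
    tibble::as_tibble(crowncluster:::features_to_row(af)))
  feats3 <- dplyr::bind_rows(feats, arow)
  expect_equal(outlier_mean_weight_rank(feats3, "zz_alien")$rank, 1L)

  expect_error(outlier_mean_weight_rank(feats, "nope"),
               class = "crowncluster_invalid_arg")
})

test_that("community-size isolation separates aliens from twins at high beta", {
  # beta = 0.7 isolates an extreme outlier only once the pruned share can
  # absorb every non-within-species edge, hence the larger reference set
  forest <- small_forest(seed = 16L, n = 8L)
  feats <- extract_forest_features(forest)
  twin <- feats[1L, ]
  twin$tree_id <- "zz_twin"
  feats2 <- dplyr::bind_rows(feats, twin)
  expect_gt(outlier_community_size(feats2, "zz_twin"), 0L)

  alien <- species_profile("alien", c(6, 0.2, 5, 0.2, 6, 0.1), c(40, 45),
                           trunk_fraction = 0.02, density = 2,
                           asymmetry = 1.5, noise_sd = 0.8)
  atree <- sample_tree(alien, seed = 2L, tree_id = "zz_alien")
  arow <- dplyr::bind_cols(
    tibble::tibble(tree_id = "zz_alien", species = "alien"),
    tibble::as_tibble(crowncluster:::features_to_row(extract_features(atree))))
  feats3 <- dplyr::bind_rows(feats, arow)
  s1 <- outlier_community_size(feats3, "zz_alien", beta = 0.7)
  s2 <- outlier_community_size(feats3, "zz_alien", beta = 0.7)
  expect_identical(s1, s2)
  expect_equal(s1, 0L)
})
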