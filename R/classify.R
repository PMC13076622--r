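#' Label communities by majority vote over a small labelled sample
#'
#' Semi-automatic species classification: from each detected community,
#' uniformly sample (without replacement) up to `k_per_community` trees with
#' known ground truth, label the whole community with the plurality species of
#' the sample (ties go to the lexicographically smallest species), and
#' propagate that label to the unsampled members. Sampled trees keep their own
#' ground-truth label, matching the manual-labelling workflow. Each community
#' draws from an independent child seed of `seed`, so trials are reproducible.
#'
#' @param communities A `tree_communities` object or assignment tibble.
#' @param labels Ground-truth species: a named vector or `tree_id`/`species`
#'   tibble. Every community must contain at least one labelled tree.
#' @param k_per_community Trees sampled per community (default 1). With
#'   `k_per_community >=` community size, voting is sampling-free.
#' @param seed Master seed for the per-community draws.
#' @return A `vote_result` list: `predicted` tibble (`tree_id`, `community`,
#'   `predicted_species`), `community_labels` tibble (`community`, `species`,
#'   `n_sampled`, `votes`).
#' @export
majority_vote <- function(communities, labels, k_per_community = 1L,
                          seed = 1L) {
  assignment <- if (inherits(communities, "tree_communities")) {
    communities$assignment
  } else {
    communities
  }
  truth <- as_labels(labels)
  truth <- truth[!is.na(truth)]
  comm_ids <- sort(unique(assignment$community))
  labelled <- purrr::map(comm_ids, function(cid) {
    members <- assignment$tree_id[assignment$community == cid]
    cands <- sort(intersect(members, names(truth)))
    if (length(cands) == 0L) {
      abort(paste0("community ", cid, " has no ground-truth labels"),
            class = "crowncluster_no_labels")
    }
    k <- min(k_per_community, length(cands))
    sampled <- with_seed(derive_seed(seed, cid + 1L),
                         sort(sample(cands, k)))
    votes <- table(truth[sampled])
    winner <- sort(names(votes)[votes == max(votes)])[1L]
    list(
      community = tibble(community = cid, species = winner,
                         n_sampled = k,
                         votes = paste(sprintf("%s=%d", names(votes),
                                               as.integer(votes)),
                                       collapse = ";")),
      sampled = sampled
    )
  })
  comm_tbl <- dplyr::bind_rows(purrr::map(labelled, "community"))
  sampled_ids <- unlist(purrr::map(labelled, "sampled"))
  predicted <- assignment %>%
    dplyr::left_join(comm_tbl[, c("community", "species")],
                     by = "community") %>%
    dplyr::rename(predicted_species = "species")
  keep <- predicted$tree_id %in% sampled_ids
  predicted$predicted_species[keep] <-
    unname(truth[predicted$tree_id[keep]])
  structure(
    list(predicted = predicted, community_labels = comm_tbl),
    class = "vote_result"
  )
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result> %d trees, %d communities\n",
              nrow(x$predicted), nrow(x$community_labels)))
  print(x$community_labels)
  invisible(x)
}

#' Mean-weight outlier score of a candidate tree
#'
#' Scores how unlike the reference set a tree is, in feature space alone:
#' rank-product edge weights are computed over the union of reference trees
#' and candidate on the complete (unpruned) pair set, each tree gets the mean
#' weight of its connections to all other trees, and trees are ranked
#' ascending by that mean with competition ties. Rank 1 marks the tree least
#' similar to all others — an injected outlier in a homogeneous set lands
#' there.
#'
#' @param features A feature tibble containing the candidate and >= 2
#'   reference trees.
#' @param candidate `tree_id` of the tree to score.
#' @param alpha Rank-contrast exponent (default 2).
#' @param feature_subset Feature sets to fuse.
#' @return A one-row tibble: `tree_id`, `mean_weight`, `rank`, `n_trees`.
#' @export
outlier_mean_weight_rank <- function(features, candidate, alpha = 2,
                                     feature_subset = FEATURE_SETS) {
  if (!candidate %in% features$tree_id) {
    abort(paste0("candidate '", candidate, "' not in feature table"),
          class = "crowncluster_invalid_arg")
  }
  if (nrow(features) < 3L) {
    abort("need at least 2 reference trees", class = "crowncluster_invalid_arg")
  }
  pairs <- pair_distances(features, feature_subset)
  weighted <- edge_weights(pairs, alpha = alpha,
                           feature_subset = feature_subset)
  mw <- tapply(c(weighted$weight, weighted$weight),
               c(weighted$u, weighted$v), mean)
  ranks <- competition_rank(as.numeric(mw))
  i <- which(names(mw) == candidate)
  tibble(tree_id = candidate, mean_weight = as.numeric(mw[i]),
         rank = ranks[i], n_trees = length(mw))
}

#' Community-size outlier score of a candidate tree
#'
#' Runs the full graph build and community detection on the union of
#' reference trees and candidate at an aggressive pruning level (`beta = 0.7`
#' by default, enough to strand weakly connected outliers) and returns how
#' many other trees share the candidate's community. 0 means the candidate is
#' isolated — a strong outlier signal.
#'
#' @inheritParams outlier_mean_weight_rank
#' @param beta Pruning share used for the outlier run (default 0.7).
#' @return Integer: size of the candidate's community excluding the candidate.
#' @export
outlier_community_size <- function(features, candidate, alpha = 2,
                                   beta = 0.7,
                                   feature_subset = FEATURE_SETS) {
  if (!candidate %in% features$tree_id) {
    abort(paste0("candidate '", candidate, "' not in feature table"),
          class = "crowncluster_invalid_arg")
  }
  graph <- build_tree_graph(features, alpha = alpha, beta = beta,
                            feature_subset = feature_subset)
  comm <- suppressWarnings(detect_communities(graph))
  asg <- comm$assignment
  cid <- asg$community[asg$tree_id == candidate]
  sum(asg$community == cid) - 1L
}
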