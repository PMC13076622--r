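#' Run the full species-clustering pipeline
#'
#' Feature extraction, rank-product graph construction, fast greedy community
#' detection, and — when ground-truth species are available — RI/ARI scoring
#' and optional majority-vote classification, in one call. Either a forest
#' table (point clouds) or a precomputed feature table can be supplied;
#' starting from features skips extraction and yields identical downstream
#' artifacts.
#'
#' @param forest A forest tibble (`tree_id`, `species`, `points`); ignored if
#'   `features` is given.
#' @param features Optional precomputed feature tibble.
#' @param delta Voxel edge length (m, default 0.5).
#' @param alpha Rank-contrast exponent (default 2).
#' @param beta Edge-pruning share (default 0.1).
#' @param feature_subset Feature sets to use (ablation runs use subsets).
#' @param n_coef Spline coefficients per profile (default 6).
#' @param method Community detector, `"fastgreedy"` or `"leiden"`.
#' @param vote_k If not `NULL`, run [majority_vote()] with this many sampled
#'   trees per community and score the resulting classification.
#' @param seed Seed for stochastic stages (Leiden, vote sampling).
#' @return A `crowncluster_run` list: `features`, `graph`, `communities`,
#'   `agreement` (RI/ARI tibble or `NULL`), `vote`, `classification`, and the
#'   resolved `config`.
#' @examples
#' forest <- simulate_forest(profile_pack("default10")[1:3],
#'                           n_per_species = 4, seed = 7)
#' run <- run_pipeline(forest)
#' run$agreement
#' @export
run_pipeline <- function(forest = NULL, features = NULL, delta = 0.5,
                         alpha = 2, beta = 0.1,
                         feature_subset = FEATURE_SETS, n_coef = 6L,
                         method = "fastgreedy", vote_k = NULL, seed = 1L) {
  if (is.null(features)) {
    stopifnot(!is.null(forest))
    features <- extract_forest_features(forest, delta = delta,
                                        n_coef = n_coef)
  }
  graph <- build_tree_graph(features, alpha = alpha, beta = beta,
                            feature_subset = feature_subset)
  communities <- detect_communities(graph, method = method, seed = seed)
  truth <- NULL
  if ("species" %in% names(features) && any(!is.na(features$species))) {
    truth <- stats::setNames(features$species, features$tree_id)
    truth <- truth[!is.na(truth)]
  }
  agreement <- NULL
  vote <- NULL
  classification <- NULL
  if (!is.null(truth)) {
    agreement <- partition_agreement(communities$assignment, truth)
    if (!is.null(vote_k)) {
      vote <- majority_vote(communities, truth, k_per_community = vote_k,
                            seed = seed)
      classification <- classification_scores(
        truth,
        stats::setNames(vote$predicted$predicted_species,
                        vote$predicted$tree_id),
        class_order = sort(unique(truth)))
    }
  }
  structure(
    list(features = features, graph = graph, communities = communities,
         agreement = agreement, vote = vote,
         classification = classification,
         config = list(delta = delta, alpha = alpha, beta = beta,
                       feature_subset = feature_subset, n_coef = n_coef,
                       method = method, vote_k = vote_k, seed = seed)),
    class = "crowncluster_run"
  )
}

#' @export
print.crowncluster_run <- function(x, ...) {
  print(x$communities)
  if (!is.null(x$agreement)) {
    cat(sprintf("  RI = %.3f, ARI = %.3f (n = %d)\n",
                x$agreement$rand_index, x$agreement$adjusted_rand_index,
                x$agreement$n_items))
  }
  invisible(x)
}

#' Sweep the alpha/beta parameter grid
#'
#' Re-runs graph construction and community detection for every (alpha, beta)
#' grid point on cached features, scoring each partition against ground truth.
#'
#' @param features A feature tibble with a `species` column.
#' @param alpha_grid,beta_grid Numeric grids (non-empty).
#' @param feature_subset Feature sets to use.
#' @param method Community detector.
#' @return A tibble with one row per grid point: `alpha`, `beta`,
#'   `rand_index`, `adjusted_rand_index`, `n_communities`, `modularity`,
#'   `all_weights_one` (graph metadata: every retained edge weight equals 1,
#'   the alpha = 0 regime).
#' @export
sweep_alpha_beta <- function(features, alpha_grid, beta_grid,
                             feature_subset = FEATURE_SETS,
                             method = "fastgreedy") {
  stopifnot(length(alpha_grid) >= 1L, length(beta_grid) >= 1L)
  truth <- stats::setNames(features$species, features$tree_id)
  pairs <- pair_distances(features, feature_subset)
  grid <- tidyr::expand_grid(alpha = alpha_grid, beta = beta_grid)
  purrr::pmap(grid, function(alpha, beta) {
    weighted <- edge_weights(pairs, alpha = alpha,
                             feature_subset = feature_subset)
    graph <- structure(
      list(edges = prune_edges(weighted, beta = beta),
           nodes = sort(features$tree_id), alpha = alpha, beta = beta,
           feature_subset = feature_subset),
      class = "tree_graph")
    comm <- suppressWarnings(detect_communities(graph, method = method))
    agg <- partition_agreement(comm$assignment, truth)
    tibble(alpha = alpha, beta = beta,
           rand_index = agg$rand_index,
           adjusted_rand_index = agg$adjusted_rand_index,
           n_communities = comm$n_communities,
           modularity = comm$modularity,
           all_weights_one = nrow(graph$edges) > 0 &&
             all(graph$edges$weight == 1))
  }) %>% dplyr::bind_rows()
}

#' Density / rotation / voxel-size robustness experiment
#'
#' Generates one base synthetic forest, then for every combination of point
#' density, rotation flag, voxel size and repeat draws a fresh per-tree
#' decimation (uniform random subsample to the stated density) and optionally
#' a fresh per-tree random vertical-axis rotation, runs the full pipeline, and
#' records the agreement with the generator labels. The base clouds are fixed
#' across repeats so the spread measures the perturbation, not the forest.
#' The long-format result feeds boxplots of ARI by density and voxel size.
#'
#' @param profiles Profile list or pack name for [simulate_forest()].
#' @param densities Fractions in (0, 1\] of points to keep.
#' @param rotations Apply random rotations (single flag or vector to cross).
#' @param voxel_sizes Voxel edge lengths (m) to evaluate.
#' @param repeats Repeats per combination (fresh decimation/rotation draws).
#' @param n_per_species Trees per species.
#' @param seed Master seed.
#' @param alpha,beta Graph parameters.
#' @return A tibble: `density`, `rotated`, `delta`, `repeat_id`,
#'   `rand_index`, `adjusted_rand_index`, `n_communities`.
#' @export
robustness_experiment <- function(profiles, densities = c(1, 0.1),
                                  rotations = FALSE, voxel_sizes = 0.5,
                                  repeats = 1L, n_per_species = 10L,
                                  seed = 1L, alpha = 2, beta = 0.1) {
  stopifnot(repeats >= 1L)
  if (is.character(profiles)) profiles <- profile_pack(profiles)
  base <- simulate_forest(profiles, n_per_species = n_per_species,
                          seed = seed)
  grid <- tidyr::expand_grid(density = densities, rotated = rotations,
                             delta = voxel_sizes,
                             repeat_id = seq_len(repeats))
  purrr::pmap(grid, function(density, rotated, delta, repeat_id) {
    tag <- repeat_id * 1000L + round(density * 100) + rotated * 7L
    forest <- base
    forest$points <- purrr::imap(base$points, function(pts, i) {
      child <- derive_seed(seed, tag * 1000L + i)
      if (rotated) {
        pts <- rotate_points(pts, with_seed(child,
                                            stats::runif(1L, 0, 2 * pi)))
      }
      if (density < 1) {
        pts <- decimate_points(pts, density, child + 1L)
      }
      pts
    })
    run <- run_pipeline(forest, delta = delta, alpha = alpha, beta = beta)
    tibble(density = density, rotated = rotated, delta = delta,
           repeat_id = repeat_id,
           rand_index = run$agreement$rand_index,
           adjusted_rand_index = run$agreement$adjusted_rand_index,
           n_communities = run$communities$n_communities)
  }) %>% dplyr::bind_rows()
}
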