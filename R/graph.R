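FEATURE_SETS <- c("f1", "f2", "f3", "f4", "f5", "f6")

#' Distance between two trees on one feature
#'
#' Scalar features use the absolute difference; vector features use the cosine
#' distance `1 - cos(fu, fv)`, which ignores overall scale — the property that
#' makes the per-slice point-count feature robust to point density.
#'
#' @param fu,fv Two feature values: both scalars, or both vectors of equal
#'   length and nonzero norm.
#' @return A non-negative scalar (vector distances lie in \[0, 2\]).
#' @export
feature_distance <- function(fu, fv) {
  stopifnot(length(fu) == length(fv))
  if (length(fu) == 1L) {
    return(abs(fu - fv))
  }
  nu <- sqrt(sum(fu^2))
  nv <- sqrt(sum(fv^2))
  if (nu == 0 || nv == 0) {
    abort("cosine distance undefined for a zero-norm feature vector",
          class = "crowncluster_zero_norm")
  }
  1 - sum(fu * fv) / (nu * nv)
}

# Pairwise distances for every tree pair and every active feature set.
# Returns a tibble of unordered distinct pairs (u < v lexicographically) with
# one distance column per feature.
pair_distances <- function(features, feature_subset = FEATURE_SETS) {
  stopifnot(nrow(features) >= 2L, all(feature_subset %in% FEATURE_SETS))
  features <- dplyr::arrange(features, .data$tree_id)
  ids <- features$tree_id
  n <- length(ids)
  pi_ <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pj_ <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  out <- tibble(u = ids[pi_], v = ids[pj_])
  for (f in feature_subset) {
    cols <- grep(paste0("^", f, "(_|$)"), names(features), value = TRUE)
    X <- as.matrix(features[, cols, drop = FALSE])
    if (ncol(X) == 1L) {
      d <- abs(X[pi_, 1L] - X[pj_, 1L])
    } else {
      nrm <- sqrt(rowSums(X^2))
      zero <- which(nrm == 0)
      if (length(zero) > 0L) {
        abort(sprintf("zero-norm feature '%s' for tree '%s'",
                      f, ids[zero[1L]]),
              class = "crowncluster_zero_norm")
      }
      Xn <- X / nrm
      cs <- tcrossprod(Xn)
      d <- 1 - cs[cbind(pi_, pj_)]
    }
    out[[f]] <- pmax(d, 0)
  }
  out
}

#' Competition ranks of one feature's pairwise distances
#'
#' Ascending standard competition ranking ("1224"): tied distances share the
#' smallest applicable rank and the next distinct value skips ahead.
#'
#' @param distances Numeric vector of pairwise distances for one feature.
#' @return A list with integer `ranks` and `max_rank`.
#' @export
rank_distances <- function(distances) {
  stopifnot(length(distances) >= 1L)
  r <- competition_rank(distances)
  list(ranks = r, max_rank = max(r))
}

#' Rank-product edge weights
#'
#' Fuses per-feature distance ranks into one edge weight per tree pair:
#' `w_uv = prod_f (1 - R_f(u,v) / maxR_f)^alpha`. Ranks rather than raw
#' distances make incommensurable feature scales comparable, and the product
#' means a pair must be close on every active feature to earn a high weight;
#' `alpha` sharpens the contrast between small and large ranks (`alpha = 0`
#' sets every weight to 1, leaving only graph topology).
#'
#' @param pairs A pair-distance tibble from `pair_distances()` (columns `u`,
#'   `v`, one distance column per feature).
#' @param alpha Non-negative contrast exponent (default 2).
#' @param feature_subset Features to fuse (default: all present).
#' @return The pairs tibble with a `weight` column in \[0, 1\] plus the
#'   alpha-independent rank product `base` that orders edges for pruning.
#' @export
edge_weights <- function(pairs, alpha = 2,
                         feature_subset = intersect(FEATURE_SETS, names(pairs))) {
  if (alpha < 0) {
    abort("alpha must be >= 0", class = "crowncluster_invalid_arg")
  }
  stopifnot(length(feature_subset) >= 1L,
            all(feature_subset %in% names(pairs)))
  base <- rep(1, nrow(pairs))
  for (f in feature_subset) {
    rk <- rank_distances(pairs[[f]])
    base <- base * (1 - rk$ranks / rk$max_rank)
  }
  out <- pairs[, c("u", "v")]
  out$base <- base
  out$weight <- base^alpha
  out
}

#' Discard the lowest-weight share of edges
#'
#' Sorts edges ascending by the rank-product ordering (the `base` column when
#' present, otherwise the weight; ties by lexicographic tree-id pair) and
#' removes the first `floor(beta * |E|)`. The rank product orders edges
#' identically to the weights for any `alpha > 0` and keeps the ordering
#' informative at `alpha = 0`, where every weight flattens to 1 and only the
#' surviving topology carries signal. Zero-product edges (some feature at its
#' maximum rank) are always removed — they carry no modularity signal — and
#' count toward the pruned share first.
#'
#' @param edges Tibble with columns `u`, `v`, `weight` (and optionally
#'   `base`).
#' @param beta Fraction of edges to discard, in \[0, 1).
#' @return The retained edges (`u`, `v`, `weight`), sorted by (`u`, `v`).
#' @export
prune_edges <- function(edges, beta = 0.1) {
  if (beta < 0 || beta >= 1) {
    abort("beta must be in [0, 1)", class = "crowncluster_invalid_arg")
  }
  key <- edges$base %||% edges$weight
  n_e <- nrow(edges)
  n_drop <- max(floor(beta * n_e), sum(key == 0))
  ord <- order(key, edges$u, edges$v)
  keep <- ord[setdiff(seq_len(n_e), seq_len(n_drop))]
  out <- edges[sort(keep), , drop = FALSE]
  out$base <- NULL
  dplyr::arrange(out, .data$u, .data$v)
}

#' Build the weighted tree graph from a feature table
#'
#' Composes pairwise feature distances, competition ranking, rank-product
#' weighting, and beta-pruning into the undirected tree graph used for
#' community detection.
#'
#' @param features A feature tibble from [extract_forest_features()] or
#'   [read_feature_json()] (>= 2 trees).
#' @param alpha Rank-contrast exponent (default 2).
#' @param beta Share of lowest-weight edges to discard (default 0.1).
#' @param feature_subset Feature sets to use, a subset of
#'   `c("f1", ..., "f6")`; subsets drive ablation runs.
#' @return A `tree_graph`: list with `edges` (tibble `u`, `v`, `weight`),
#'   `nodes`, and the `alpha`, `beta`, `feature_subset` metadata.
#' @export
build_tree_graph <- function(features, alpha = 2, beta = 0.1,
                             feature_subset = FEATURE_SETS) {
  stopifnot(nrow(features) >= 2L)
  pairs <- pair_distances(features, feature_subset)
  weighted <- edge_weights(pairs, alpha = alpha,
                           feature_subset = feature_subset)
  kept <- prune_edges(weighted, beta = beta)
  structure(
    list(edges = kept, nodes = sort(features$tree_id),
         alpha = alpha, beta = beta, feature_subset = feature_subset),
    class = "tree_graph"
  )
}

#' @export
print.tree_graph <- function(x, ...) {
  cat(sprintf(
    "<tree_graph> %d nodes, %d edges (alpha = %g, beta = %g, features = %s)\n",
    length(x$nodes), nrow(x$edges), x$alpha, x$beta,
    paste(x$feature_subset, collapse = ",")))
  invisible(x)
}

#' Write / read a tree graph as a TSV edge list
#'
#' Format: a `# alpha=<a> beta=<b> features=<f1,...>` header line, a
#' `# nodes=` line preserving isolated nodes, then one `u<TAB>v<TAB>weight`
#' line per edge.
#'
#' @param graph A `tree_graph`.
#' @param path Output path.
#' @return `write_graph_tsv()`: `path`, invisibly. `read_graph_tsv()`: a
#'   `tree_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  header <- c(
    sprintf("# alpha=%.10g beta=%.10g features=%s", graph$alpha, graph$beta,
            paste(graph$feature_subset, collapse = ",")),
    sprintf("# nodes=%s", paste(graph$nodes, collapse = ","))
  )
  body <- sprintf("%s\t%s\t%.17g", graph$edges$u, graph$edges$v,
                  graph$edges$weight)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  meta_line <- hdr[grepl("alpha=", hdr)][1L]
  alpha <- as.numeric(sub(".*alpha=([^ ]+).*", "\\1", meta_line))
  beta <- as.numeric(sub(".*beta=([^ ]+).*", "\\1", meta_line))
  feats <- strsplit(sub(".*features=([^ ]+).*", "\\1", meta_line), ",")[[1L]]
  node_line <- hdr[grepl("nodes=", hdr)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  edges <- if (length(body) > 0L) {
    parts <- strsplit(body, "\t")
    tibble(u = vapply(parts, `[`, "", 1L),
           v = vapply(parts, `[`, "", 2L),
           weight = as.numeric(vapply(parts, `[`, "", 3L)))
  } else {
    tibble(u = character(), v = character(), weight = double())
  }
  nodes <- if (length(node_line) > 0L) {
    strsplit(sub(".*nodes=", "", node_line[1L]), ",")[[1L]]
  } else {
    sort(unique(c(edges$u, edges$v)))
  }
  structure(
    list(edges = edges, nodes = sort(nodes), alpha = alpha, beta = beta,
         feature_subset = feats),
    class = "tree_graph"
  )
}
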