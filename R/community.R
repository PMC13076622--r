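#' Weighted modularity of a partition
#'
#' `Q = sum_c (e_c - a_c^2)`, where `e_c` is the fraction of total edge weight
#' falling inside community `c` and `a_c` the fraction of total weighted
#' degree attached to `c`.
#'
#' @param graph A `tree_graph` from [build_tree_graph()].
#' @param assignment A named integer vector or a tibble with columns
#'   `tree_id`, `community`, covering every node.
#' @return Q in \[-1, 1\].
#' @export
graph_modularity <- function(graph, assignment) {
  memb <- as_membership(assignment, graph$nodes)
  e <- graph$edges
  m <- sum(e$weight)
  if (m <= 0) {
    abort("total edge weight is zero; modularity undefined",
          class = "crowncluster_empty_graph")
  }
  cu <- memb[e$u]
  cv <- memb[e$v]
  e_c <- tapply(e$weight[cu == cv], cu[cu == cv], sum) / m
  deg <- tapply(c(e$weight, e$weight), c(e$u, e$v), sum)
  a_c <- tapply(deg, memb[names(deg)], sum) / (2 * m)
  sum(e_c) - sum(a_c^2)
}

as_membership <- function(assignment, nodes) {
  if (is.data.frame(assignment)) {
    memb <- stats::setNames(assignment$community, assignment$tree_id)
  } else {
    memb <- assignment
  }
  if (!all(nodes %in% names(memb))) {
    abort("assignment does not cover every node",
          class = "crowncluster_invalid_arg")
  }
  memb[nodes]
}

#' Detect species communities on the tree graph
#'
#' The default detector is the weighted fast greedy modularity optimisation
#' (Clauset–Newman–Moore agglomeration): starting from singleton communities,
#' repeatedly merge the community pair with the largest modularity gain while
#' any gain is positive, breaking ties by the smallest community-index pair so
#' results are fully deterministic. Isolated nodes end up as singleton
#' communities. An optional Leiden back-end (via the igraph package) is
#' available for comparison; it is stochastic and takes a seed and resolution.
#'
#' @param graph A `tree_graph`.
#' @param method `"fastgreedy"` (default, deterministic) or `"leiden"`.
#' @param seed Seed for the Leiden back-end.
#' @param resolution Resolution parameter for the Leiden back-end.
#' @return A `tree_communities` object: `assignment` tibble (`tree_id`,
#'   `community` with contiguous indices from 0), `modularity`,
#'   `n_communities`, `method`. An edgeless graph yields all singletons with
#'   modularity reported as 0 and a warning.
#' @examples
#' forest <- simulate_forest(profile_pack("default10")[1:3],
#'                           n_per_species = 4, seed = 1)
#' feats <- extract_forest_features(forest)
#' comm <- detect_communities(build_tree_graph(feats))
#' glance(comm)
#' @export
detect_communities <- function(graph, method = c("fastgreedy", "leiden"),
                               seed = 1L, resolution = 1) {
  method <- match.arg(method)
  nodes <- graph$nodes
  n <- length(nodes)
  stopifnot(n >= 1L)
  if (nrow(graph$edges) == 0L || sum(graph$edges$weight) <= 0) {
    warn("edgeless graph: every node is a singleton community; Q reported as 0")
    return(new_tree_communities(
      stats::setNames(seq_len(n) - 1L, nodes), modularity = 0,
      method = method, degenerate = TRUE))
  }
  memb <- if (method == "fastgreedy") {
    fast_greedy_membership(graph)
  } else {
    leiden_membership(graph, seed = seed, resolution = resolution)
  }
  q <- graph_modularity(graph, memb)
  new_tree_communities(memb, modularity = q, method = method)
}

# Weighted CNM greedy agglomeration on a dense community-pair weight matrix.
# Merge gain for communities i != j is dQ = 2 * (E_ij - a_i a_j); merging adds
# rows/cols and keeps the smaller community index, so tie-breaking by smallest
# (i, j) is well defined and deterministic.
fast_greedy_membership <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  m <- sum(graph$edges$weight)
  E <- matrix(0, n, n)
  eu <- idx[graph$edges$u]
  ev <- idx[graph$edges$v]
  w <- graph$edges$weight / (2 * m)
  for (r in seq_along(w)) {
    E[eu[r], ev[r]] <- E[eu[r], ev[r]] + w[r]
    E[ev[r], eu[r]] <- E[ev[r], eu[r]] + w[r]
  }
  a <- rowSums(E)
  self <- rep(0, n)
  comm <- seq_len(n)           # current community of each original node
  active <- rep(TRUE, n)
  repeat {
    dq <- 2 * (E - outer(a, a))
    dq[!active, ] <- -Inf
    dq[, !active] <- -Inf
    diag(dq) <- -Inf
    best <- max(dq)
    if (!is.finite(best) || best <= 1e-15) break
    hits <- which(dq == best, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    pick <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    i <- pick[1L]
    j <- pick[2L]
    # merge j into i
    self[i] <- self[i] + self[j] + 2 * E[i, j]
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[i, i] <- 0
    E[j, ] <- 0
    E[, j] <- 0
    a[i] <- a[i] + a[j]
    a[j] <- 0
    active[j] <- FALSE
    comm[comm == j] <- i
  }
  stats::setNames(comm, nodes)
}

leiden_membership <- function(graph, seed, resolution) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the leiden back-end requires the 'igraph' package",
          class = "crowncluster_missing_backend")
  }
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", weights = igraph::E(g)$weight,
    resolution = resolution)$membership)
  stats::setNames(memb, graph$nodes)
}

new_tree_communities <- function(memb, modularity, method,
                                 degenerate = FALSE) {
  nodes <- sort(names(memb))
  memb <- memb[nodes]
  relabel <- stats::setNames(seq_along(unique(memb)) - 1L,
                             as.character(unique(memb)))
  assignment <- tibble(tree_id = nodes,
                       community = unname(relabel[as.character(memb)]))
  structure(
    list(assignment = assignment,
         modularity = modularity,
         n_communities = length(relabel),
         method = method,
         degenerate = degenerate),
    class = "tree_communities"
  )
}

#' @export
print.tree_communities <- function(x, ...) {
  cat(sprintf("<tree_communities> %d trees in %d communities (Q = %.4f, %s)\n",
              nrow(x$assignment), x$n_communities, x$modularity, x$method))
  invisible(x)
}

#' Tidy a community assignment into one row per tree
#'
#' @param x A `tree_communities` object.
#' @param ... Unused.
#' @return A tibble with columns `tree_id`, `community`.
#' @method tidy tree_communities
#' @export
tidy.tree_communities <- function(x, ...) {
  x$assignment
}

#' One-row summary of a community detection fit
#'
#' @param x A `tree_communities` object.
#' @param ... Unused.
#' @return A tibble with `n_trees`, `n_communities`, `modularity`, `method`.
#' @method glance tree_communities
#' @export
glance.tree_communities <- function(x, ...) {
  tibble(n_trees = nrow(x$assignment), n_communities = x$n_communities,
         modularity = x$modularity, method = x$method)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write / read a partition CSV (`tree_id,community`)
#'
#' @param communities A `tree_communities` object or an assignment tibble.
#' @param path Output path.
#' @return `write_partition_csv()`: `path`, invisibly.
#'   `read_partition_csv()`: an assignment tibble.
#' @export
write_partition_csv <- function(communities, path) {
  tbl <- if (inherits(communities, "tree_communities")) {
    communities$assignment
  } else {
    communities
  }
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(tree_id = "c",
                                                community = "i"),
                  progress = FALSE)
}
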