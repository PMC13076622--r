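# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# Pair-counting Rand / Adjusted Rand: enumerate every item pair.
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  agree <- 0
  s11 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
      if (same_a && same_b) s11 <- s11 + 1
    }
  }
  total <- n * (n - 1) / 2
  tab <- table(a, b)
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  expected <- s_a * s_b / total
  denom <- (s_a + s_b) / 2 - expected
  list(ri = agree / total,
       ari = if (denom == 0) 1 else (s11 - expected) / denom)
}

# All set partitions of n items (n small), as integer label vectors.
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (g in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, g)
    }
  }
  out
}

# Exhaustive maximum-modularity partition of a small weighted edge list.
oracle_best_modularity <- function(nodes, edges) {
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- oracle_modularity(edges, memb)
    if (q > best) best <- q
  }
  best
}

# Direct evaluation of Q = sum_c (e_c - a_c^2) from the edge list.
oracle_modularity <- function(edges, memb) {
  m <- sum(edges$weight)
  intra <- sum(edges$weight[memb[edges$u] == memb[edges$v]]) / m
  deg <- tapply(c(edges$weight, edges$weight), c(edges$u, edges$v), sum)
  a <- tapply(deg, memb[names(deg)], sum) / (2 * m)
  intra - sum(a^2)
}

# Normal-equations least squares for the spline design (independent of the
# package's SVD solve).
oracle_spline_fit <- function(B, y) {
  solve(crossprod(B), crossprod(B, y))
}

# Exhaustive symmetric-grid scan: every point against every voxel centre of a
# candidate grid, applying the two inequalities literally.
oracle_symmetrize_counts <- function(points, grid_s) {
  cx <- grid_s$centre[1L]; cy <- grid_s$centre[2L]
  delta <- grid_s$delta
  counts <- array(0L, dim = grid_s$dims)
  for (p in seq_len(nrow(points))) {
    lx <- points$x[p]; ly <- points$y[p]; lz <- points$z[p]
    rl <- sqrt((lx - cx)^2 + (ly - cy)^2)
    for (i in seq_len(grid_s$dims[1L])) {
      sx <- grid_s$origin[1L] + (i - 0.5) * delta
      for (j in seq_len(grid_s$dims[2L])) {
        sy <- grid_s$origin[2L] + (j - 0.5) * delta
        rs <- sqrt((sx - cx)^2 + (sy - cy)^2)
        if (abs(rl - rs) >= delta) next
        for (k in seq_len(grid_s$dims[3L])) {
          sz <- grid_s$origin[3L] + (k - 0.5) * delta
          own <- floor((lz - grid_s$origin[3L]) / delta) == k - 1L
          if (abs(lz - sz) < 0.5 * delta || own) {
            counts[i, j, k] <- counts[i, j, k] + 1L
          }
        }
      }
    }
  }
  counts
}

# Small, fast forest shared by several tests (3 well-separated species).
small_forest <- function(seed = 42L, n = 4L) {
  profs <- lapply(profile_pack("default10")[c(1L, 3L, 5L)], function(p) {
    p$density <- p$density / 5  # ~1k points per tree keeps tests quick
    p
  })
  simulate_forest(profs, n_per_species = n, seed = seed)
}

rigid_motion <- function(points, seed) {
  set.seed(seed)
  th <- stats::runif(3L, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3L, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3L, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[3]), -sin(th[3]),
                 0, sin(th[3]), cos(th[3])), 3L, byrow = TRUE)
  shift <- stats::runif(3L, -50, 50)
  m <- as.matrix(points[, c("x", "y", "z")]) %*% t(Rz %*% Ry %*% Rx)
  tibble::tibble(x = m[, 1L] + shift[1L], y = m[, 2L] + shift[2L],
                 z = m[, 3L] + shift[3L])
}
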