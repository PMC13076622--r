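#' Voxelize a tree point cloud
#'
#' Builds the axis-aligned count grid V with isotropic voxel edge `delta`.
#' Each point falls in exactly one voxel by half-open intervals
#' `[origin + i*delta, origin + (i+1)*delta)`, so V's counts sum to the number
#' of points. The grid origin is the bounding-box minimum snapped so that the
#' cloud's centre of mass lies at a voxel centre in x and y; this makes the
#' radial symmetrisation condition symmetric about the vertical axis and the
#' axis-only degenerate case exact.
#'
#' @param points A tibble with columns `x`, `y`, `z` (metres, z up).
#' @param delta Voxel edge length in metres (> 0).
#' @return A `voxel_grid`: list with `delta`, `origin`, `dims`, a dense 3D
#'   `counts` array, and `centre` (the centre of mass of the points).
#' @export
voxelize <- function(points, delta = 0.5) {
  stopifnot(delta > 0)
  m <- assert_points(points)
  centre <- colMeans(m)
  mins <- apply(m, 2L, min)
  maxs <- apply(m, 2L, max)
  snap <- function(cc, lo) {
    k <- ceiling((cc - lo) / delta - 0.5)
    cc - (k + 0.5) * delta
  }
  origin <- c(snap(centre[1L], mins[1L]), snap(centre[2L], mins[2L]), mins[3L])
  dims <- pmax(1L, as.integer(floor((maxs - origin) / delta)) + 1L)
  idx <- floor(sweep(m, 2L, origin) / delta)
  idx <- pmin(pmax(idx, 0L), matrix(rep(dims - 1L, each = nrow(m)), ncol = 3L))
  lin <- 1L + idx[, 1L] + dims[1L] * (idx[, 2L] + dims[2L] * idx[, 3L])
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  structure(
    list(delta = delta, origin = unname(origin), dims = unname(dims),
         counts = counts, centre = unname(centre)),
    class = "voxel_grid"
  )
}

#' Symmetrize a voxel grid around the vertical axis
#'
#' Builds the rotationally symmetric grid S by revolving the points around
#' the vertical axis through the centre of mass, in the spirit of a surface
#' of revolution: a point at horizontal radius `r` from the axis is counted
#' into every voxel of its z-slice whose centre sits at a radius within
#' `delta` of `r` (`||l_xy - c_xy| - |s_xy - c_xy|| < delta`,
#' `|l_z - s_z| < delta/2`). S shares `delta`, z-layering and centre with V;
#' its horizontal extent is a square generous enough to hold every reachable
#' ring voxel.
#'
#' @param points The same point cloud the grid was built from.
#' @param grid The `voxel_grid` V from [voxelize()].
#' @return A `voxel_grid` holding the S counts (same class, shared z-layers).
#' @export
symmetrize <- function(points, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  m <- assert_points(points)
  delta <- grid$delta
  centre <- grid$centre
  r_pt <- sqrt((m[, 1L] - centre[1L])^2 + (m[, 2L] - centre[2L])^2)
  half <- as.integer(ceiling(max(r_pt) / delta)) + 2L
  n_xy <- 2L * half + 1L
  origin <- c(centre[1L] - (half + 0.5) * delta,
              centre[2L] - (half + 0.5) * delta,
              grid$origin[3L])
  nz <- grid$dims[3L]
  # radial distance of every S voxel centre from the vertical axis
  off <- (seq_len(n_xy) - 1L - half) * delta
  rho <- sqrt(outer(off^2, off^2, "+"))
  zbin <- floor((m[, 3L] - origin[3L]) / delta)
  zbin <- pmin(pmax(zbin, 0L), nz - 1L)
  counts <- array(0L, dim = c(n_xy, n_xy, nz))
  rho_v <- as.vector(rho)
  for (k in sort(unique(zbin))) {
    r_k <- r_pt[zbin == k]
    hits <- rowSums(abs(outer(rho_v, r_k, "-")) < delta)
    counts[, , k + 1L] <- counts[, , k + 1L] + as.integer(hits)
  }
  structure(
    list(delta = delta, origin = unname(origin),
         dims = c(n_xy, n_xy, nz), counts = counts,
         centre = unname(centre)),
    class = "voxel_grid"
  )
}

# Occupied voxels of a grid as integer offsets from the vertical axis through
# the centre of mass (i, j) and the shared z-slice index k. Both V and S have
# the centre at a voxel centre in x/y with a common delta and z origin, so
# these keys live in one index space.
occupied_keys <- function(grid) {
  occ <- which(grid$counts >= 1L, arr.ind = TRUE)
  if (nrow(occ) == 0L) {
    return(tibble(i = integer(), j = integer(), k = integer()))
  }
  xc <- grid$origin[1L] + (occ[, 1L] - 0.5) * grid$delta
  yc <- grid$origin[2L] + (occ[, 2L] - 0.5) * grid$delta
  tibble(
    i = as.integer(round((xc - grid$centre[1L]) / grid$delta)),
    j = as.integer(round((yc - grid$centre[2L]) / grid$delta)),
    k = as.integer(occ[, 3L] - 1L)
  )
}

key_strings <- function(keys) paste(keys$i, keys$j, keys$k, sep = ",")

#' Jaccard index of two voxel sets
#'
#' `|A intersect B| / |A union B|` over a common index space. Inputs are
#' either logical vectors/arrays of identical shape or atomic vectors of set
#' member keys. An empty union (two empty sets) is defined as 1: identical
#' empty sets are identical.
#'
#' @param a,b Logical vectors/arrays of equal shape, or key vectors.
#' @return A scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    stopifnot(length(a) == length(b))
    uni <- sum(a | b)
    if (uni == 0L) return(1)
    return(sum(a & b) / uni)
  }
  a <- unique(a)
  b <- unique(b)
  uni <- length(union(a, b))
  if (uni == 0L) return(1)
  length(intersect(a, b)) / uni
}

#' Rotational-symmetry feature f2
#'
#' Jaccard index between the binarised voxel grid and its symmetrised
#' counterpart (occupancy, count >= 1). Because every occupied V voxel is also
#' occupied in S, this equals `|V(b)| / |S(b)|`; 1 means a perfectly
#' rotationally symmetric crown.
#'
#' @param grid_v The `voxel_grid` V.
#' @param grid_s The matching symmetrised grid S.
#' @return A scalar in (0, 1\].
#' @export
symmetry_feature <- function(grid_v, grid_s) {
  kv <- key_strings(occupied_keys(grid_v))
  ks <- key_strings(occupied_keys(grid_s))
  if (length(kv) == 0L) {
    abort("empty voxel grid", class = "crowncluster_empty_input")
  }
  jaccard_index(kv, ks)
}

#' Per-slice shape profiles from V and S
#'
#' For every horizontal z-slice shared by V and S: the Jaccard index between
#' the binarised slices (per-slice rotational symmetry), the total S point
#' count of the slice, and the maximum horizontal distance of raw points in
#' the slice from the central vertical axis. Slices empty in both grids are
#' dropped from all three profiles (they are artefacts of the voxel size, and
#' the Jaccard index is undefined on an empty union).
#'
#' @param points The tree's point cloud.
#' @param grid_v,grid_s Grids from [voxelize()] and [symmetrize()].
#' @return A tibble with columns `slice`, `z_mid`, `jaccard`, `n_points`,
#'   `max_radius`, one row per non-empty slice.
#' @export
slice_profiles <- function(points, grid_v, grid_s) {
  m <- assert_points(points)
  delta <- grid_v$delta
  nz <- grid_v$dims[3L]
  kv <- occupied_keys(grid_v)
  ks <- occupied_keys(grid_s)
  r_pt <- sqrt((m[, 1L] - grid_v$centre[1L])^2 +
               (m[, 2L] - grid_v$centre[2L])^2)
  zbin <- floor((m[, 3L] - grid_v$origin[3L]) / delta)
  zbin <- pmin(pmax(zbin, 0L), nz - 1L)
  s_slice_sum <- apply(grid_s$counts, 3L, sum)
  rows <- purrr::map(seq_len(nz) - 1L, function(k) {
    v_k <- key_strings(kv[kv$k == k, ])
    s_k <- key_strings(ks[ks$k == k, ])
    if (length(v_k) == 0L && length(s_k) == 0L) return(NULL)
    in_slice <- zbin == k
    tibble(
      slice = k,
      z_mid = grid_v$origin[3L] + (k + 0.5) * delta,
      jaccard = jaccard_index(v_k, s_k),
      n_points = s_slice_sum[k + 1L],
      max_radius = if (any(in_slice)) max(r_pt[in_slice]) else 0
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) {
    abort("all slices empty", class = "crowncluster_empty_input")
  }
  out
}
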