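test_that("pca_feature matches known geometries and is rigid-motion invariant", {
  seg <- tibble::tibble(x = 0, y = 0, z = c(-2, 2))  # sd exactly 2*sqrt(2)
  s <- stats::sd(c(-2, 2))
  expect_equal(pca_feature(seg), c(s, s, 0), tolerance = 1e-12)

  set.seed(1)
  iso <- tibble::tibble(x = rnorm(1e5), y = rnorm(1e5), z = rnorm(1e5))
  expect_true(all(abs(pca_feature(iso)) < 0.05))

  set.seed(2)
  aniso <- tibble::tibble(x = 3 * rnorm(2e4), y = 2 * rnorm(2e4),
                          z = rnorm(2e4))
  # independent oracle: eigen-decomposition of the covariance
  ev <- sqrt(eigen(stats::cov(as.matrix(aniso)))$values)
  expect_equal(pca_feature(aniso),
               c(ev[1] - ev[2], ev[1] - ev[3], ev[2] - ev[3]),
               tolerance = 1e-9)

  cloud <- small_forest(seed = 8L, n = 1L)$points[[1L]]
  f0 <- pca_feature(cloud)
  for (s in 1:5) {
    expect_equal(pca_feature(rigid_motion(cloud, s)), f0, tolerance = 1e-9)
  }
  expect_error(pca_feature(cloud[1, ]), class = "crowncluster_empty_input")
})

test_that("voxelize assigns points by half-open intervals and conserves counts", {
  delta <- 1
  # 8 points at centres of 8 distinct voxels of a 2x2x2 block
  centres <- expand.grid(x = c(0.5, 1.5), y = c(0.5, 1.5), z = c(0.5, 1.5))
  g <- voxelize(tibble::as_tibble(centres), delta)
  expect_equal(sum(g$counts), 8L)
  expect_equal(sum(g$counts == 1L), 8L)

  # boundary point: half-open convention puts it in the upper voxel of z
  pts <- tibble::tibble(x = c(0.25, 0.25), y = c(0.25, 0.25), z = c(0, 1))
  gz <- voxelize(pts, delta)
  zidx <- floor((pts$z - gz$origin[3]) / delta)
  expect_equal(zidx, c(0, 1))

  forest <- small_forest(seed = 2L, n = 1L)
  for (p in forest$points) {
    expect_equal(sum(voxelize(p, 0.5)$counts), nrow(p))
  }
  expect_error(voxelize(tibble::tibble(x = NA_real_, y = 1, z = 1), 0.5),
               class = "crowncluster_invalid_points")
})

test_that("symmetrize matches the exhaustive two-inequality scan", {
  # single off-axis point plus axis points: ring structure
  pts <- tibble::tibble(
    x = c(rep(0, 20), 1.0),
    y = c(rep(0, 20), 0),
    z = c(seq(0.05, 1.95, length.out = 20), 1.0))
  delta <- 0.5
  g <- voxelize(pts, delta)
  s <- symmetrize(pts, g)
  expect_equal(s$counts, oracle_symmetrize_counts(pts, s))

  cloud <- small_forest(seed = 5L, n = 1L)$points[[1L]]
  cloud <- cloud[1:60, ]  # keep the O(P * V) oracle affordable
  g2 <- voxelize(cloud, 0.5)
  s2 <- symmetrize(cloud, g2)
  expect_equal(s2$counts, oracle_symmetrize_counts(cloud, s2))
})

test_that("binarised V is contained in binarised S on generated trees", {
  forest <- small_forest(seed = 7L, n = 2L)
  for (p in forest$points) {
    g <- voxelize(p, 0.5)
    s <- symmetrize(p, g)
    kv <- crowncluster:::key_strings(crowncluster:::occupied_keys(g))
    ks <- crowncluster:::key_strings(crowncluster:::occupied_keys(s))
    expect_true(all(kv %in% ks))
    # f2 equals the ratio form |V(b)| / |S(b)| given the inclusion
    expect_equal(symmetry_feature(g, s), length(kv) / length(unique(ks)))
  }
})

test_that("jaccard index follows the set definition", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(), character()), 1)
  expect_equal(jaccard_index(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE)), 1 / 3)
})

test_that("axis-only trees are perfectly symmetric at every level", {
  pts <- tibble::tibble(x = rep(0, 40), y = rep(0, 40),
                        z = seq(0.01, 3.99, length.out = 40))
  g <- voxelize(pts, 0.5)
  s <- symmetrize(pts, g)
  expect_equal(symmetry_feature(g, s), 1)
  prof <- slice_profiles(pts, g, s)
  expect_true(all(prof$jaccard == 1))
  expect_true(all(prof$max_radius < 0.5 / sqrt(2)))
})

test_that("slice profiles have consistent lengths and conserve S counts", {
  cloud <- small_forest(seed = 4L, n = 1L)$points[[1L]]
  g <- voxelize(cloud, 0.5)
  s <- symmetrize(cloud, g)
  prof <- slice_profiles(cloud, g, s)
  expect_true(all(prof$jaccard >= 0 & prof$jaccard <= 1))
  expect_equal(sum(prof$n_points), sum(s$counts))
  expect_true(nrow(prof) <= g$dims[3L])
})

test_that("spline fits agree with a normal-equations oracle", {
  set.seed(10)
  y <- rnorm(40)
  x <- seq_len(40)
  fit <- fit_profile_spline(y, x = x)
  B <- crowncluster:::spline_basis((x - 1) / 39, 6L)
  expect_equal(fit$coefficients, as.vector(oracle_spline_fit(B, y)),
               tolerance = 1e-8)
  expect_equal(fit$residual_l1, sum(abs(B %*% fit$coefficients - y)),
               tolerance = 1e-10)

  # profile already in the basis span -> zero residual
  coefs <- c(0.2, 1, -0.5, 2, 0.3, 1.5)
  y_in <- as.vector(B %*% coefs)
  fit_in <- fit_profile_spline(y_in, x = x)
  expect_lt(fit_in$residual_l1, 1e-8)
  expect_equal(fit_in$coefficients, coefs, tolerance = 1e-8)

  # constant profile: partition of unity makes every coefficient the constant
  fit_c <- fit_profile_spline(rep(3.25, 25))
  expect_equal(fit_c$coefficients, rep(3.25, 6L), tolerance = 1e-8)
  expect_lt(fit_c$residual_l1, 1e-8)

  # shorter than the basis: exact minimum-norm interpolation
  fit_s <- fit_profile_spline(c(1, 2, 1.5), x = c(0, 1, 2))
  expect_lt(fit_s$residual_l1, 1e-8)

  expect_error(fit_profile_spline(numeric()),
               class = "crowncluster_empty_input")
})

test_that("extract_features yields 23 finite components with documented invariances", {
  cloud <- small_forest(seed = 6L, n = 1L)$points[[1L]]
  fv <- extract_features(cloud)
  expect_length(unlist(fv[c("f1", "f2", "f3", "f4", "f5", "f6")]), 23L)
  expect_true(all(is.finite(unlist(fv))))
  expect_gt(fv$f2, 0)
  expect_lte(fv$f2, 1)
  expect_gte(fv$f6, 0)

  shifted <- dplyr::mutate(cloud, x = x + 100, y = y - 50, z = z + 7)
  fs <- extract_features(shifted)
  expect_equal(unlist(fs), unlist(fv), tolerance = 1e-6)

  rot <- rotate_points(cloud, pi / 2)
  fr <- extract_features(rot)
  expect_equal(fr$f1, fv$f1, tolerance = 1e-9)
  for (nm in c("f2", "f3", "f4", "f5", "f6")) {
    expect_equal(unlist(fr[[nm]]), unlist(fv[[nm]]), tolerance = 0.05,
                 ignore_attr = TRUE)
  }

  expect_error(extract_features(cloud[1:5, ]),
               class = "crowncluster_tiny_tree")
})

test_that("duplicating points leaves f2/f3/f5/f6 unchanged and scales f4 linearly", {
  cloud <- small_forest(seed = 12L, n = 1L)$points[[1L]]
  fv <- extract_features(cloud)
  doubled <- dplyr::bind_rows(cloud, cloud)
  fd <- extract_features(doubled)
  expect_equal(fd$f2, fv$f2)
  expect_equal(fd$f3, fv$f3, tolerance = 1e-9)
  expect_equal(fd$f5, fv$f5, tolerance = 1e-9)
  expect_equal(fd$f6, fv$f6, tolerance = 1e-9)
  expect_equal(fd$f4, 2 * fv$f4, tolerance = 1e-9)
  # hence the downstream cosine distance on f4 is density-invariant
  expect_equal(feature_distance(fd$f4, fv$f4), 0, tolerance = 1e-12)
})
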