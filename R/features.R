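#' PCA spread feature f1
#'
#' Principal component analysis on the mean-centred 3D coordinates; `d1 >= d2
#' >= d3` are the standard deviations of the point projections onto the three
#' principal directions, and the feature is their pairwise differences
#' `[d1 - d2, d1 - d3, d2 - d3]`. All components are non-negative, and the
#' feature is exactly invariant to any rigid rotation or translation of the
#' cloud. Rank-deficient clouds are allowed: missing directions contribute a
#' zero standard deviation.
#'
#' @param points A tibble with columns `x`, `y`, `z` (>= 2 points).
#' @return Numeric 3-vector.
#' @examples
#' seg <- tibble::tibble(x = 0, y = 0, z = c(-2, 0, 2))
#' pca_feature(seg)
#' @export
pca_feature <- function(points) {
  m <- assert_points(points)
  if (nrow(m) < 2L) {
    abort("pca_feature needs at least 2 points",
          class = "crowncluster_empty_input")
  }
  d <- sort(prcomp(m, center = TRUE, scale. = FALSE)$sdev,
            decreasing = TRUE)
  d <- c(d, 0, 0)[1:3]
  c(d[1L] - d[2L], d[1L] - d[3L], d[2L] - d[3L])
}

spline_basis <- function(x, n_coef = 6L) {
  stopifnot(n_coef >= 4L)
  inner <- if (n_coef > 4L) seq(0, 1, length.out = n_coef - 2L)[-c(1L, n_coef - 2L)] else numeric()
  knots <- c(rep(0, 4L), inner, rep(1, 4L))
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

#' Compress a per-slice profile into cubic B-spline coefficients
#'
#' Fits an unpenalised cubic B-spline with exactly `n_coef` basis functions
#' (uniform open knot vector on \[0, 1\]) to a profile sampled at slice
#' midpoints, by linear least squares. The abscissae are the midpoints
#' rescaled to \[0, 1\], so profiles of different lengths land in one
#' coefficient space. Profiles shorter than the basis are fitted by the
#' minimum-norm least-squares solution (SVD pseudoinverse), which is exact and
#' deterministic.
#'
#' @param values Profile values, one per slice.
#' @param x Optional abscissae (e.g. slice mid heights); defaults to equally
#'   spaced positions. Rescaled internally to \[0, 1\].
#' @param n_coef Number of basis functions (default 6).
#' @return A list with `coefficients` (length `n_coef`) and `residual_l1`
#'   (the absolute sum of fitting differences).
#' @export
fit_profile_spline <- function(values, x = NULL, n_coef = 6L) {
  n <- length(values)
  if (n < 1L) {
    abort("profile must have at least one slice",
          class = "crowncluster_empty_input")
  }
  if (is.null(x)) x <- seq_len(n)
  stopifnot(length(x) == n)
  if (n == 1L) {
    x01 <- 0.5
  } else {
    rng <- range(x)
    x01 <- (x - rng[1L]) / (rng[2L] - rng[1L])
  }
  B <- spline_basis(x01, n_coef)
  sv <- svd(B)
  pos <- sv$d > max(sv$d) * 1e-12
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], values)) / sv$d[pos])
  fit <- as.vector(B %*% coef)
  list(coefficients = as.vector(coef), residual_l1 = sum(abs(fit - values)))
}

#' Extract the 23-component shape descriptor of one tree
#'
#' Runs the full per-tree feature pipeline: PCA spreads (f1, 3 components),
#' voxelisation and symmetrisation, the rotational-symmetry Jaccard measure
#' (f2, 1), per-slice symmetry / point-count / maximum-radius profiles
#' compressed to 6 cubic B-spline coefficients each (f3, f4, f5), and the L1
#' residual of the symmetry-profile fit (f6, 1). All quantities are computed
#' relative to the centre of mass, so the descriptor is invariant to
#' translation and (up to voxelisation effects) to rotation about the
#' vertical axis.
#'
#' @param points A tree point cloud tibble (>= 10 points spanning >= 2
#'   occupied z-slices).
#' @param delta Voxel edge length in metres (default 0.5).
#' @param n_coef Spline coefficients per profile (default 6).
#' @return A named list of class `tree_features` with elements `f1` (3), `f2`
#'   (scalar), `f3`, `f4`, `f5` (6 each), `f6` (scalar).
#' @export
extract_features <- function(points, delta = 0.5, n_coef = 6L) {
  m <- assert_points(points)
  if (nrow(m) < 10L) {
    abort("tree too small: fewer than 10 points",
          class = "crowncluster_tiny_tree")
  }
  f1 <- pca_feature(points)
  V <- voxelize(points, delta)
  S <- symmetrize(points, V)
  prof <- slice_profiles(points, V, S)
  if (nrow(prof) < 2L) {
    abort("tree too small: fewer than 2 occupied z-slices",
          class = "crowncluster_tiny_tree")
  }
  f2 <- symmetry_feature(V, S)
  s3 <- fit_profile_spline(prof$jaccard, x = prof$z_mid, n_coef = n_coef)
  s4 <- fit_profile_spline(prof$n_points, x = prof$z_mid, n_coef = n_coef)
  s5 <- fit_profile_spline(prof$max_radius, x = prof$z_mid, n_coef = n_coef)
  out <- list(f1 = f1, f2 = f2, f3 = s3$coefficients, f4 = s4$coefficients,
              f5 = s5$coefficients, f6 = s3$residual_l1)
  if (!all(is.finite(unlist(out)))) {
    abort("non-finite feature component", class = "crowncluster_invalid_feature")
  }
  structure(out, class = "tree_features")
}

feature_colnames <- function(n_coef = 6L) {
  c(paste0("f1_", 1:3), "f2",
    paste0("f3_", seq_len(n_coef)), paste0("f4_", seq_len(n_coef)),
    paste0("f5_", seq_len(n_coef)), "f6")
}

features_to_row <- function(fv) {
  vals <- c(fv$f1, fv$f2, fv$f3, fv$f4, fv$f5, fv$f6)
  stats::setNames(as.list(vals), feature_colnames(length(fv$f3)))
}

row_to_features <- function(row, n_coef = 6L) {
  g <- function(prefix, k) as.numeric(row[paste0(prefix, "_", seq_len(k))])
  structure(
    list(f1 = g("f1", 3L), f2 = as.numeric(row[["f2"]]),
         f3 = g("f3", n_coef), f4 = g("f4", n_coef), f5 = g("f5", n_coef),
         f6 = as.numeric(row[["f6"]])),
    class = "tree_features"
  )
}

#' Extract features for every tree in a forest
#'
#' @param forest A forest tibble (`tree_id`, `species`, `points`), e.g. from
#'   [read_forest()] or [simulate_forest()].
#' @param delta Voxel edge length in metres.
#' @param n_coef Spline coefficients per profile.
#' @return A tibble with `tree_id`, `species`, and the 23 numeric feature
#'   columns `f1_1 ... f6`, one row per tree in `tree_id` order.
#' @export
extract_forest_features <- function(forest, delta = 0.5, n_coef = 6L) {
  stopifnot(all(c("tree_id", "points") %in% names(forest)))
  rows <- purrr::map2(forest$tree_id, forest$points, function(id, pts) {
    fv <- tryCatch(
      extract_features(pts, delta = delta, n_coef = n_coef),
      error = function(e) {
        abort(paste0("feature extraction failed for tree '", id, "': ",
                     conditionMessage(e)),
              class = "crowncluster_feature_error", parent = e)
      }
    )
    dplyr::bind_cols(tibble(tree_id = id), as_tibble(features_to_row(fv)))
  })
  out <- dplyr::bind_rows(rows)
  if ("species" %in% names(forest)) {
    out <- dplyr::left_join(forest[, c("tree_id", "species")], out,
                            by = "tree_id")
  }
  dplyr::arrange(out, .data$tree_id)
}

#' Write / read per-tree feature vectors as JSON
#'
#' The schema is a JSON object keyed by tree id, each entry holding `f1`
#' (array of 3), `f2` (number), `f3`, `f4`, `f5` (arrays of 6), `f6` (number)
#' and optionally `species`. `read_feature_json()` validates the schema by
#' default; `strict = FALSE` gives a best-effort importer for externally
#' produced files with the same six named fields (extra fields are ignored,
#' values are coerced to numeric).
#'
#' @param features A feature tibble from [extract_forest_features()].
#' @param path JSON file path.
#' @return `write_feature_json()`: `path`, invisibly. `read_feature_json()`:
#'   a feature tibble.
#' @export
write_feature_json <- function(features, path) {
  n_coef <- sum(grepl("^f3_", names(features)))
  obj <- purrr::map(seq_len(nrow(features)), function(i) {
    row <- features[i, ]
    fv <- row_to_features(row, n_coef)
    ent <- list(f1 = fv$f1, f2 = fv$f2, f3 = fv$f3, f4 = fv$f4, f5 = fv$f5,
                f6 = fv$f6)
    if (!is.null(row$species) && !is.na(row$species)) {
      ent$species <- row$species
    }
    ent
  })
  names(obj) <- features$tree_id
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_json
#' @param strict Validate the schema strictly (default) or import
#'   best-effort.
#' @export
read_feature_json <- function(path, strict = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lens <- c(f1 = 3L, f2 = 1L, f3 = 6L, f4 = 6L, f5 = 6L, f6 = 1L)
  rows <- purrr::imap(obj, function(ent, id) {
    for (fld in names(lens)) {
      if (!fld %in% names(ent)) {
        abort(sprintf("tree '%s': missing field '%s'", id, fld),
              class = "crowncluster_schema_error")
      }
      v <- suppressWarnings(as.numeric(unlist(ent[[fld]])))
      if (strict && length(v) != lens[[fld]]) {
        abort(sprintf("tree '%s': field '%s' has length %d, expected %d",
                      id, fld, length(v), lens[[fld]]),
              class = "crowncluster_schema_error")
      }
      if (length(v) != lens[[fld]]) {
        v <- rep_len(v, lens[[fld]])
      }
      if (!all(is.finite(v))) {
        abort(sprintf("tree '%s': non-finite value in '%s'", id, fld),
              class = "crowncluster_validation_error")
      }
      ent[[fld]] <- v
    }
    fv <- structure(ent[c("f1", "f2", "f3", "f4", "f5", "f6")],
                    class = "tree_features")
    dplyr::bind_cols(
      tibble(tree_id = id,
             species = as.character(ent$species %||% NA_character_)),
      as_tibble(features_to_row(fv))
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$tree_id)
}
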