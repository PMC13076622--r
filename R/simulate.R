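#' Define a species profile for the synthetic forest simulator
#'
#' A species is modelled as a solid of revolution: crown radius as a function
#' of normalised height, given by six control radii interpolated piecewise
#' linearly, sitting on a bare trunk segment. Azimuthal asymmetry modulates
#' the radius as `r(z) * (1 + asymmetry * cos(azimuth - phase))` with a random
#' per-tree phase, and isotropic Gaussian jitter models measurement noise.
#' Crown radii scale proportionally with the drawn tree height so trees of one
#' species share a shape, not a size.
#'
#' @param species_id Species label.
#' @param radius_profile Six control radii (m), crown base to crown top.
#' @param height_range Length-2 numeric, min/max total tree height (m), min > 0.
#' @param trunk_fraction Fraction of total height below the crown, in \[0, 1).
#' @param density Points per cubic metre of crown volume. `NULL` auto-computes
#'   the density that yields `target_points` expected crown points at the mean
#'   height of `height_range`.
#' @param asymmetry Amplitude of the azimuthal radius modulation (>= 0);
#'   0 gives a perfectly rotationally symmetric crown.
#' @param noise_sd Standard deviation (m) of isotropic Gaussian point jitter.
#' @param target_points Expected crown point count used when `density` is
#'   `NULL`.
#' @return A `species_profile` list.
#' @export
species_profile <- function(species_id, radius_profile, height_range,
                            trunk_fraction = 0.2, density = NULL,
                            asymmetry = 0.1, noise_sd = 0.05,
                            target_points = 5000) {
  stopifnot(length(radius_profile) == 6L, all(radius_profile >= 0),
            length(height_range) == 2L, height_range[1L] > 0,
            height_range[2L] >= height_range[1L],
            trunk_fraction >= 0, trunk_fraction < 1, asymmetry >= 0,
            noise_sd >= 0)
  p <- structure(
    list(species_id = as.character(species_id),
         radius_profile = as.numeric(radius_profile),
         height_range = as.numeric(height_range),
         trunk_fraction = trunk_fraction,
         density = density, asymmetry = asymmetry, noise_sd = noise_sd),
    class = "species_profile"
  )
  if (is.null(p$density)) {
    vol <- crown_volume(p, mean(height_range))
    if (vol <= 0) {
      abort("cannot auto-set density for a zero-volume crown",
            class = "crowncluster_invalid_profile")
    }
    p$density <- target_points / vol
  }
  if (p$density <= 0) {
    abort("density must be positive", class = "crowncluster_invalid_profile")
  }
  p
}

#' Analytic crown volume of a species profile
#'
#' Volume of the solid of revolution defined by the piecewise-linear radius
#' profile at a given total height, including the mean azimuthal modulation
#' factor `1 + asymmetry^2 / 2`.
#'
#' @param profile A [species_profile()].
#' @param height Total tree height (m); default the mean of `height_range`.
#' @return Volume in cubic metres.
#' @export
crown_volume <- function(profile, height = mean(profile$height_range)) {
  r <- profile$radius_profile * height / mean(profile$height_range)
  crown_len <- height * (1 - profile$trunk_fraction)
  dz <- crown_len / (length(r) - 1L)
  # exact integral of pi * r(z)^2 over each linear segment
  segs <- pi * dz * (r[-length(r)]^2 + r[-length(r)] * r[-1L] + r[-1L]^2) / 3
  sum(segs) * (1 + profile$asymmetry^2 / 2)
}

radius_at <- function(profile, u, height) {
  scale <- height / mean(profile$height_range)
  stats::approx(seq(0, 1, length.out = length(profile$radius_profile)),
                profile$radius_profile * scale, xout = u, rule = 2)$y
}

# trunk hit rate along the stem, points per metre
TRUNK_RATE <- 40

#' Sample one synthetic tree point cloud
#'
#' Draws the tree height uniformly within the profile's `height_range`, fills
#' the crown solid volumetrically with an expected `density * volume` Poisson
#' point count (terrestrial LiDAR returns occur throughout crowns, and the
#' per-slice point-count feature needs interior mass), adds a sparse vertical
#' trunk segment, applies the azimuthal asymmetry with a random phase, and
#' jitters all points with isotropic Gaussian noise.
#'
#' @param profile A [species_profile()].
#' @param seed Integer seed; the same `(profile, seed)` pair always yields an
#'   identical cloud.
#' @param tree_id Identifier; defaults to the species id plus the seed.
#' @return A tree point cloud tibble (`x`, `y`, `z`) with `tree_id` and
#'   `species` attributes.
#' @export
sample_tree <- function(profile, seed, tree_id = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  with_seed(seed, {
    height <- stats::runif(1L, profile$height_range[1L],
                           profile$height_range[2L])
    crown_base <- height * profile$trunk_fraction
    crown_len <- height - crown_base
    vol <- crown_volume(profile, height)
    n_crown <- stats::rpois(1L, profile$density * vol)
    phase <- stats::runif(1L, 0, 2 * pi)

    pts <- NULL
    if (n_crown > 0L) {
      # inverse-CDF sample of z with density proportional to r(z)^2
      grid <- seq(0, 1, length.out = 513L)
      w <- radius_at(profile, (grid[-1L] + grid[-513L]) / 2, height)^2
      if (sum(w) <= 0) {
        n_crown <- 0L
      } else {
        bin <- sample.int(512L, n_crown, replace = TRUE, prob = w)
        u <- (bin - stats::runif(n_crown)) / 512
        z <- crown_base + u * crown_len
        theta <- stats::runif(n_crown, 0, 2 * pi)
        rmax <- radius_at(profile, u, height) *
          (1 + profile$asymmetry * cos(theta - phase))
        rho <- pmax(rmax, 0) * sqrt(stats::runif(n_crown))
        pts <- cbind(rho * cos(theta), rho * sin(theta), z)
      }
    }
    n_trunk <- if (crown_base > 0) stats::rpois(1L, TRUNK_RATE * crown_base) else 0L
    if (n_trunk > 0L) {
      tz <- stats::runif(n_trunk, 0, crown_base)
      pts <- rbind(pts, cbind(0, 0, tz))
    }
    if (is.null(pts) || nrow(pts) == 0L) {
      abort(paste0("profile '", profile$species_id,
                   "' produced zero points; increase density"),
            class = "crowncluster_empty_input")
    }
    if (profile$noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, profile$noise_sd),
                          ncol = 3L)
    }
    new_tree(tibble(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]),
             tree_id = tree_id %||% paste0(profile$species_id, "_", seed),
             species = profile$species_id)
  })
}

#' Rotate a point cloud about the vertical axis through its centroid
#'
#' @param points A tibble with columns `x`, `y`, `z`.
#' @param angle Rotation angle in radians.
#' @return The rotated tibble (other columns and attributes preserved).
#' @export
rotate_points <- function(points, angle) {
  cx <- mean(points$x)
  cy <- mean(points$y)
  dx <- points$x - cx
  dy <- points$y - cy
  out <- points
  out$x <- cx + cos(angle) * dx - sin(angle) * dy
  out$y <- cy + sin(angle) * dx + cos(angle) * dy
  out
}

#' Uniformly subsample a point cloud to a fraction of its points
#'
#' Keeps `floor(fraction * n)` points (at least one), drawn uniformly without
#' replacement.
#'
#' @param points A tibble with columns `x`, `y`, `z`.
#' @param fraction Fraction in (0, 1] of points to keep.
#' @param seed Integer seed for the draw.
#' @return The subsampled tibble.
#' @export
decimate_points <- function(points, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(points)
  keep <- max(1L, floor(fraction * n))
  if (keep == n) return(points)
  with_seed(seed, points[sort(sample.int(n, keep)), , drop = FALSE])
}

#' Simulate a labelled synthetic forest
#'
#' Generates `n_per_species` trees for each profile, each from an independent
#' child seed derived from `seed`, optionally applying a uniform random
#' vertical-axis rotation and uniform random decimation to each tree —
#' the two perturbations used to probe rotation and point-density robustness.
#'
#' @param profiles List of [species_profile()]s (at least two for clustering
#'   experiments), or a pack name accepted by [profile_pack()].
#' @param n_per_species Trees per species: a single integer or one per
#'   profile. Ignored in favour of a pack's own class sizes when `profiles` is
#'   a pack name carrying them and `n_per_species` is `NULL`.
#' @param seed Master integer seed.
#' @param rotate Apply a uniform random rotation in \[0, 2*pi) per tree.
#' @param decimate Fraction in (0, 1] of points to keep per tree.
#' @return A forest tibble (`tree_id`, `species`, `points`), sorted by
#'   `tree_id`, with exactly balanced labels when `n_per_species` is scalar.
#' @examples
#' forest <- simulate_forest(profile_pack("default10"), n_per_species = 2,
#'                           seed = 1)
#' dplyr::count(forest, species)
#' @export
simulate_forest <- function(profiles, n_per_species = NULL, seed = 1L,
                            rotate = FALSE, decimate = 1) {
  if (is.character(profiles)) profiles <- profile_pack(profiles)
  stopifnot(length(profiles) >= 1L)
  if (is.null(n_per_species)) {
    n_per_species <- attr(profiles, "n_per_species") %||% 10L
  }
  if (length(n_per_species) == 1L) {
    n_per_species <- rep(as.integer(n_per_species), length(profiles))
  }
  stopifnot(length(n_per_species) == length(profiles))
  if (any(n_per_species < 1L)) {
    abort("n_per_species must be >= 1", class = "crowncluster_invalid_arg")
  }
  counter <- 0L
  rows <- purrr::map2(profiles, n_per_species, function(p, n) {
    purrr::map(seq_len(n), function(i) {
      counter <<- counter + 1L
      id <- sprintf("%s_%03d", p$species_id, i)
      tree <- sample_tree(p, derive_seed(seed, counter), tree_id = id)
      if (rotate) {
        ang <- with_seed(derive_seed(seed, counter + 100000L),
                         stats::runif(1L, 0, 2 * pi))
        tree <- rotate_points(tree, ang)
      }
      if (decimate < 1) {
        tree <- decimate_points(tree, decimate,
                                derive_seed(seed, counter + 200000L))
      }
      tibble(tree_id = id, species = p$species_id,
             points = list(tibble(x = tree$x, y = tree$y, z = tree$z)))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows)) %>% dplyr::arrange(.data$tree_id)
}

#' Named packs of synthetic species profiles
#'
#' Two calibrated study sets ship with the package:
#'
#' * `"default10"`: ten well-separated crown archetypes (spire and columnar
#'   conifers, globular, vase-shaped and umbrella broadleaves, a layered
#'   cedar, a strongly asymmetric weeping form, ...), around 5000 points per
#'   tree at full density. Species are distinct enough that the full pipeline
#'   should recover them perfectly.
#' * `"hard7"`: seven overlapping broadleaf/conifer profiles with higher
#'   noise and asymmetry and imbalanced class sizes
#'   (164/183/22/39/158/25/100), emulating the difficulty of a real
#'   terrestrial-LiDAR campaign where species merge.
#'
#' @param name `"default10"` or `"hard7"`.
#' @return A list of [species_profile()]s; `"hard7"` carries its class sizes
#'   in the `n_per_species` attribute.
#' @export
profile_pack <- function(name = c("default10", "hard7")) {
  name <- match.arg(name)
  if (name == "default10") {
    list(
      species_profile("sp01_spire",    c(2.2, 1.9, 1.5, 1.0, 0.5, 0.05), c(18, 22), 0.15,
                      asymmetry = 0.05),
      species_profile("sp02_column",   c(2.0, 2.0, 2.0, 2.0, 2.0, 1.8),  c(24, 28), 0.30,
                      asymmetry = 0),
      species_profile("sp03_globe",    c(0.5, 2.8, 3.8, 3.8, 2.8, 0.8),  c(12, 14), 0.35,
                      asymmetry = 0.1),
      species_profile("sp04_vase",     c(0.8, 1.2, 2.0, 3.2, 4.2, 3.0),  c(14, 16), 0.30,
                      asymmetry = 0.15),
      species_profile("sp05_umbrella", c(0.3, 0.5, 0.9, 1.8, 4.5, 3.5),  c(9, 11),  0.50,
                      asymmetry = 0.2),
      species_profile("sp06_dome",     c(2.5, 3.2, 3.2, 2.6, 1.6, 0.4),  c(5, 6.5), 0.05,
                      asymmetry = 0.1),
      species_profile("sp07_bilobe",   c(2.4, 0.6, 0.3, 0.6, 2.4, 1.6),  c(20, 24), 0.08,
                      asymmetry = 0.25),
      species_profile("sp08_layered",  c(3.0, 0.6, 2.4, 0.5, 1.6, 0.2),  c(15, 18), 0.45,
                      asymmetry = 0.3),
      species_profile("sp09_weeping",  c(3.8, 3.4, 2.6, 1.6, 0.8, 0.2),  c(8, 10),  0.20,
                      asymmetry = 0.5),
      species_profile("sp10_oak",      c(1.8, 3.6, 4.2, 4.2, 4.0, 2.8),  c(16, 19), 0.40,
                      asymmetry = 0.35)
    )
  } else {
    packs <- list(
      species_profile("beech",   c(0.8, 2.4, 3.4, 3.6, 3.0, 1.2), c(20, 30), 0.35,
                      asymmetry = 0.35, noise_sd = 0.15, target_points = 2000),
      species_profile("dougfir", c(2.4, 2.1, 1.7, 1.2, 0.7, 0.1), c(25, 40), 0.20,
                      asymmetry = 0.25, noise_sd = 0.15, target_points = 2000),
      species_profile("oak",     c(1.0, 2.6, 3.6, 3.8, 3.2, 1.4), c(18, 28), 0.40,
                      asymmetry = 0.45, noise_sd = 0.15, target_points = 2000),
      species_profile("ash",     c(0.9, 2.0, 3.0, 3.4, 2.8, 1.0), c(20, 30), 0.38,
                      asymmetry = 0.35, noise_sd = 0.15, target_points = 2000),
      species_profile("spruce",  c(2.2, 1.9, 1.6, 1.1, 0.6, 0.1), c(22, 38), 0.15,
                      asymmetry = 0.2, noise_sd = 0.15, target_points = 2000),
      species_profile("pine",    c(1.4, 1.7, 1.8, 1.6, 1.0, 0.3), c(20, 32), 0.45,
                      asymmetry = 0.3, noise_sd = 0.15, target_points = 2000),
      species_profile("redoak",  c(1.1, 2.5, 3.3, 3.5, 2.9, 1.2), c(18, 26), 0.36,
                      asymmetry = 0.4, noise_sd = 0.15, target_points = 2000)
    )
    attr(packs, "n_per_species") <- c(164L, 183L, 22L, 39L, 158L, 25L, 100L)
    packs
  }
}
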