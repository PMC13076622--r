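#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a community assignment against known species
#'
#' Trees are ordered by species along the x axis (dashed lines at species
#' boundaries); the y position is the detected community. A perfect
#' clustering shows one community level per species block.
#'
#' @param object A `tree_communities` object.
#' @param species Optional named species vector or `tree_id`/`species`
#'   tibble; omitted, trees are ordered by id.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tree_communities
#' @export
autoplot.tree_communities <- function(object, species = NULL, ...) {
  df <- object$assignment
  if (!is.null(species)) {
    lab <- as_labels(species)
    df$species <- unname(lab[df$tree_id])
    df <- dplyr::arrange(df, .data$species, .data$tree_id)
  } else {
    df$species <- "unknown"
  }
  df$index <- seq_len(nrow(df))
  bounds <- df %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(end = max(.data$index), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = factor(.data$community),
                                   colour = .data$species)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = utils::head(bounds$end, -1) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "tree (grouped by species)", y = "community",
                  colour = "species",
                  title = sprintf("%d communities, Q = %.3f",
                                  object$n_communities, object$modularity)) +
    ggplot2::theme_minimal()
}

#' Boxplot of clustering agreement across densities
#'
#' @param results A tibble from [robustness_experiment()].
#' @return A ggplot object: ARI by point density, faceted by voxel size when
#'   several were run, rotated runs dodged.
#' @export
plot_robustness <- function(results) {
  p <- ggplot2::ggplot(
    results,
    ggplot2::aes(x = factor(.data$density),
                 y = .data$adjusted_rand_index,
                 fill = factor(.data$rotated))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "point density (fraction kept)", y = "ARI",
                  fill = "rotated") +
    ggplot2::theme_minimal()
  if (length(unique(results$delta)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$delta),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Heatmap of clustering agreement over the alpha/beta grid
#'
#' @param sweep A tibble from [sweep_alpha_beta()].
#' @param metric Column to colour by (default `adjusted_rand_index`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "adjusted_rand_index") {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                      fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(alpha), y = expression(beta),
                  fill = metric) +
    ggplot2::theme_minimal()
}
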