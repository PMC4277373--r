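#' Barcode-gap scatter plot
#'
#' Maximum intraspecific distance against minimum distance to the nearest
#' neighbour, one point per species, with the identity line marking where the
#' gap closes. Points can be coloured by a grouping column (e.g.
#' distribution category).
#'
#' @param stats Output of [species_gap_stats()].
#' @param colour_by Optional column name in `stats` to colour points by.
#' @return A ggplot object.
#' @export
plot_barcode_gap <- function(stats, colour_by = NULL) {
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$max_intra, y = .data$nn_dist))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::aes(colour = .data[[colour_by]])
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Maximum intraspecific distance (%)",
                  y = "Minimum distance to nearest neighbour (%)")
}

#' Partition-comparison scatter plot
#'
#' Pooled nearest-neighbour distance against the reference-only value, with
#' guide lines at 0%, 10% and 20% NN-distance reduction, showing how far
#' extending geographic sampling erodes the distance to the nearest
#' neighbour.
#'
#' @param partition Output of [partition_compare()].
#' @return A ggplot object.
#' @export
plot_partition_comparison <- function(partition) {
  ggplot2::ggplot(partition,
                  ggplot2::aes(x = .data$nn_dist_ref, y = .data$nn_dist_pooled)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = 0.9, intercept = 0, colour = "red", linetype = 2) +
    ggplot2::geom_abline(slope = 0.8, intercept = 0, colour = "blue", linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "NN distance, reference region only (%)",
                  y = "NN distance, pooled regions (%)")
}

#' NN distance against sample size
#'
#' Nearest-neighbour distance per species plotted against the (log10)
#' harmonic mean of the focal and NN sample sizes, with the OLS fit overlaid.
#'
#' @param stats Output of [species_gap_stats()].
#' @return A ggplot object.
#' @export
plot_nn_samplesize <- function(stats) {
  dat <- stats[!is.na(stats$nn_dist) & !is.na(stats$harmonic_n), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data$harmonic_n), y = .data$nn_dist)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "log10 harmonic mean sample size",
                  y = "NN distance (%)")
}

#' Residual intraspecific divergence by group
#'
#' Boxplots of the sample-size-adjusted residuals of maximum intraspecific
#' distance (see [intra_vs_samplesize_residuals()]) split by a per-species
#' grouping such as distribution category or dispersal class.
#'
#' @param stats Output of [species_gap_stats()].
#' @param groups A tibble `species`, `group` assigning each species to a
#'   group; species without a group are dropped.
#' @return A ggplot object.
#' @export
plot_intra_residuals <- function(stats, groups) {
  res <- intra_vs_samplesize_residuals(stats)
  dat <- dplyr::inner_join(res, groups, by = "species")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$residual)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Residual maximum intraspecific distance (%)")
}

#' @describeIn fit_category_model Category means with 95% Wald intervals.
#' @param object A `category_fit` object.
#' @export
autoplot.category_fit <- function(object, ...) {
  if (is.null(object$category_means)) abort("Fit has no category effects to plot")
  dat <- tibble::tibble(category = names(object$category_means),
                        mean = unname(object$category_means))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = paste("Model mean of", object$response))
}
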