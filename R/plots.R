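#' Plot a droplet diameter histogram
#'
#' @param object A `size_summary` from [summarize_sizes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.size_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2,
    y = .data$count
  )) +
    ggplot2::geom_col(
      width = if (nrow(h) > 1) h$bin_right[1] - h$bin_left[1] else 1,
      fill = "steelblue", colour = "grey30"
    ) +
    ggplot2::labs(
      x = "Droplet diameter (µm)",
      y = "Count",
      title = sprintf(
        "N = %d, D_av = %.1f µm, Ð = %.1f%%",
        object$N, object$D_av_um, object$dispersity_percent
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs Poisson-expected occupancy proportions
#'
#' @param object An `occupancy_fit` from [fit_poisson()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_fit <- function(object, ...) {
  d <- tidy.occupancy_fit(object) |>
    dplyr::select("bin", observed = "observed_prop", expected = "expected_prop") |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "source", values_to = "prop")
  ggplot2::ggplot(d, ggplot2::aes(.data$bin, .data$prop, fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "Cells per droplet", y = "Proportion of droplets",
      title = sprintf("λ = %.3f (%s)", object$lambda, object$lambda_source),
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell invasion distances
#'
#' Cells are plotted by their distance from the bead surface against
#' their sphere-equivalent radius; a cell is invaded when the former
#' exceeds the latter (the dashed identity line).
#'
#' @param object An `invasion_report` from [classify_invasion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.invasion_report <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(
    x = .data$radius_um, y = .data$surface_distance_um,
    colour = .data$invaded
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Nucleus radius (µm)",
      y = "Distance from bead surface (µm)",
      title = sprintf(
        "n_b = %d, n_i = %d (%d%%), d_max = %.1f µm",
        object$n_b, object$n_i, object$percent_invaded_reported, object$d_max_um
      ),
      colour = "Invaded"
    ) +
    ggplot2::theme_minimal()
}

#' Plot maximum invasion distances by condition
#'
#' @param object A `condition_comparison` from [compare_conditions()].
#' @param data The observation-level data frame originally passed to
#'   [compare_conditions()] (optional; group means and sd are always
#'   shown).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_comparison <- function(object, data = NULL, ...) {
  g <- object$groups
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$condition, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    )) +
    ggplot2::labs(
      x = NULL, y = "Maximum invasion distance (µm)",
      title = "Mean ± SD by condition"
    ) +
    ggplot2::theme_minimal()
  p
}
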