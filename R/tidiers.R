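#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a droplet size summary
#'
#' @param x A `size_summary` from [summarize_sizes()].
#' @param ... Unused.
#' @return One row per track: `track`, `n_frames`, `diameter_um`,
#'   `counted`.
#' @export
tidy.size_summary <- function(x, ...) x$tracks

#' One-row summary of a droplet size distribution
#'
#' @param x A `size_summary`.
#' @param ... Unused.
#' @return Tibble with `N`, `D_av_um`, `sd_um`, `dispersity_percent`.
#' @export
glance.size_summary <- function(x, ...) {
  tibble::tibble(
    N = x$N,
    D_av_um = x$D_av_um,
    sd_um = x$sd_um,
    dispersity_percent = x$dispersity_percent
  )
}

#' Tidy an occupancy fit
#'
#' @param x An `occupancy_fit` from [fit_poisson()].
#' @param ... Unused.
#' @return One row per occupancy bin with observed and expected
#'   proportions.
#' @export
tidy.occupancy_fit <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(x$observed, observed_n = "n", observed_prop = "prop"),
    dplyr::rename(x$expected, expected_prop = "prop"),
    by = "bin"
  )
}

#' One-row summary of an occupancy fit
#'
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `lambda_source`, `n`, `statistic`,
#'   `df`, `p_value`.
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    lambda_source = x$lambda_source,
    n = x$n,
    statistic = x$gof$statistic,
    df = x$gof$df,
    p_value = x$gof$p_value
  )
}

#' Tidy an invasion report
#'
#' @param x An `invasion_report` from [classify_invasion()].
#' @param ... Unused.
#' @return The per-cell tibble (centroid, volume, radius, distances,
#'   invaded flag).
#' @export
tidy.invasion_report <- function(x, ...) x$cells

#' One-row summary of an invasion report
#'
#' @param x An `invasion_report`.
#' @param ... Unused.
#' @return Tibble with `n_b`, `n_i`, `n_total`, `d_max_um`,
#'   `percent_invaded`, `percent_invaded_reported`, `bead_radius_um`.
#' @export
glance.invasion_report <- function(x, ...) {
  tibble::tibble(
    n_b = x$n_b,
    n_i = x$n_i,
    n_total = x$n_b + x$n_i,
    d_max_um = x$d_max_um,
    percent_invaded = x$percent_invaded,
    percent_invaded_reported = x$percent_invaded_reported,
    bead_radius_um = x$bead$radius_um
  )
}

#' Tidy a condition comparison
#'
#' @param x A `condition_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return The pairwise t-test table joined with the Tukey-Kramer
#'   adjusted p-values.
#' @export
tidy.condition_comparison <- function(x, ...) {
  out <- x$pairwise
  if (!is.null(x$tukey)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$tukey, "group1", "group2", "diff", "p_adj"),
      by = c("group1", "group2")
    )
  }
  out
}

#' Group summaries of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return One row per condition with `n`, `mean`, `sd`.
#' @export
glance.condition_comparison <- function(x, ...) x$groups
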