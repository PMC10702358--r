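# Poisson occupancy statistics for single-cell droplet encapsulation.
# With cells arriving independently at the flow-focusing junction, the
# probability that a droplet carries k cells is P_k = lambda^k e^-lambda / k!,
# where lambda is the mean number of cells per generated droplet.

OCC_BINS <- c("0", "1", "2", "3+")

#' Poisson probability of k cells per droplet
#'
#' `P_k = lambda^k e^{-lambda} / k!`, evaluated in log space so large `k`
#' does not overflow. Vectorised over `k` and `lambda`.
#'
#' @param lambda Mean number of cells per droplet (>= 0).
#' @param k Non-negative integer cell count(s).
#' @return Probabilities in `[0, 1]`.
#' @export
poisson_pk <- function(lambda, k) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop_input("`lambda` must be finite and >= 0")
  }
  if (any(k < 0) || any(k != floor(k))) {
    stop_input("`k` must contain non-negative integers")
  }
  dpois(k, lambda)
}

#' Estimate the occupancy rate lambda from per-droplet counts
#'
#' The Poisson maximum-likelihood estimate: the arithmetic mean of the
#' per-droplet cell counts.
#'
#' @param counts Integer vector of cells per droplet, or a data frame with
#'   a `k_cells` column.
#' @return The estimate `lambda_hat` (a single number).
#' @export
estimate_lambda <- function(counts) {
  counts <- occupancy_vector(counts)
  if (length(counts) == 0L) stop_input("`counts` must contain at least one observation")
  mean(counts)
}

occupancy_vector <- function(counts) {
  if (is.data.frame(counts)) {
    if (!"k_cells" %in% names(counts)) {
      stop_input("data frame input must have a `k_cells` column")
    }
    counts <- counts$k_cells
  }
  if (length(counts) > 0L && (any(counts < 0) || any(counts != floor(counts)))) {
    stop_input("cell counts must be non-negative integers")
  }
  as.numeric(counts)
}

#' Expected occupancy proportions in the 0 / 1 / 2 / 3+ bins
#'
#' The 3+ bin is computed in closed form as `1 - P_0 - P_1 - P_2`, never
#' by truncated summation, so the four proportions always sum to one.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @return A tibble with columns `bin` ("0", "1", "2", "3+") and `prop`.
#' @export
binned_proportions <- function(lambda) {
  p012 <- poisson_pk(lambda, 0:2)
  tibble::tibble(
    bin = factor(OCC_BINS, levels = OCC_BINS),
    prop = c(p012, 1 - sum(p012))
  )
}

#' Observed occupancy proportions in the 0 / 1 / 2 / 3+ bins
#'
#' @param counts Per-droplet cell counts (vector or data frame with
#'   `k_cells`).
#' @return A tibble with columns `bin`, `n` and `prop`.
#' @export
bin_occupancy <- function(counts) {
  counts <- occupancy_vector(counts)
  if (length(counts) == 0L) stop_input("`counts` must contain at least one observation")
  kb <- pmin(counts, 3)
  n <- vapply(0:3, function(b) sum(kb == b), numeric(1))
  tibble::tibble(
    bin = factor(OCC_BINS, levels = OCC_BINS),
    n = as.integer(n),
    prop = n / sum(n)
  )
}

#' Chi-square goodness of fit of binned occupancy to a Poisson model
#'
#' Pearson chi-square over the 0/1/2/3+ bins against the closed-form
#' Poisson proportions. When `lambda` is supplied externally (e.g. from
#' junction counts) the degrees of freedom are `bins - 1`; when it is
#' estimated from the same data they are `bins - 2`. Bins with expected
#' count below `min_expected` are merged into their smaller neighbour
#' before the statistic is computed. This test is an extension beyond a
#' visual observed-vs-theoretical comparison and is labelled as such in
#' reports.
#'
#' @param counts Per-droplet cell counts (vector or data frame with
#'   `k_cells`).
#' @param lambda Optional externally supplied rate; when `NULL` the
#'   Poisson MLE of `counts` is used.
#' @param min_expected Minimum expected count per bin (default 1).
#' @return A list with `statistic`, `df`, `p_value`, `lambda`,
#'   `lambda_source` ("given" or "estimated"), `n`, `small_sample`
#'   (TRUE when n < 20) and the merged observed/expected table.
#' @export
goodness_of_fit <- function(counts, lambda = NULL, min_expected = 1) {
  counts <- occupancy_vector(counts)
  n <- length(counts)
  if (n == 0L) stop_input("`counts` must contain at least one observation")
  lambda_source <- if (is.null(lambda)) "estimated" else "given"
  if (is.null(lambda)) lambda <- mean(counts)
  obs <- bin_occupancy(counts)$n
  expd <- n * binned_proportions(lambda)$prop
  labs <- OCC_BINS
  # merge any under-populated bin into its smaller adjacent neighbour
  while (length(obs) > 2L && any(expd < min_expected)) {
    i <- which.min(expd)
    j <- if (i == 1L) 2L else if (i == length(expd)) i - 1L else {
      if (expd[i - 1L] <= expd[i + 1L]) i - 1L else i + 1L
    }
    lo <- min(i, j)
    hi <- max(i, j)
    obs[lo] <- obs[lo] + obs[hi]
    expd[lo] <- expd[lo] + expd[hi]
    labs[lo] <- paste0(labs[lo], "+", labs[hi])
    obs <- obs[-hi]
    expd <- expd[-hi]
    labs <- labs[-hi]
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L - (lambda_source == "estimated")
  df <- max(df, 1L)
  list(
    statistic = stat,
    df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    lambda = lambda,
    lambda_source = lambda_source,
    n = n,
    small_sample = n < 20L,
    table = tibble::tibble(bin = labs, observed = obs, expected = expd)
  )
}

#' Fit the Poisson occupancy model to per-droplet counts
#'
#' Bundles the rate (given or estimated), observed and expected binned
#' proportions and the goodness of fit into one object with
#' [tidy.occupancy_fit()], [glance.occupancy_fit()] and
#' [autoplot.occupancy_fit()] methods.
#'
#' @inheritParams goodness_of_fit
#' @return An `occupancy_fit` object.
#' @export
fit_poisson <- function(counts, lambda = NULL) {
  counts <- occupancy_vector(counts)
  gof <- goodness_of_fit(counts, lambda = lambda)
  structure(
    list(
      lambda = gof$lambda,
      lambda_source = gof$lambda_source,
      n = gof$n,
      observed = bin_occupancy(counts),
      expected = binned_proportions(gof$lambda),
      gof = gof
    ),
    class = "occupancy_fit"
  )
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf(
    "<occupancy_fit> n = %d droplets, lambda = %.4f (%s)\n  chi-square = %.3f on %d df, p = %.3g\n",
    x$n, x$lambda, x$lambda_source, x$gof$statistic, x$gof$df, x$gof$p_value
  ))
  invisible(x)
}

#' Fraction of droplets containing at least one cell
#'
#' `f = 1 - e^{-lambda}`, and its inverse `lambda = -log(1 - f)`.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @return Occupancy fraction in `[0, 1)`.
#' @export
occupancy_fraction <- function(lambda) {
  if (any(lambda < 0)) stop_input("`lambda` must be >= 0")
  -expm1(-lambda)
}

#' @rdname occupancy_fraction
#' @param f Occupancy fraction, `0 <= f < 1`.
#' @export
lambda_from_occupancy <- function(f) {
  if (any(f < 0) || any(f >= 1)) stop_input("`f` must satisfy 0 <= f < 1")
  -log1p(-f)
}

#' Droplet generation rate from dispersed-phase flow and droplet size
#'
#' `rate = Q / (pi D^3 / 6)` with Q in microlitres per minute and D in
#' micrometres (1 uL = 1e9 um^3), giving droplets per minute.
#'
#' @param flow_ul_min Dispersed-phase flow rate, uL/min.
#' @param diameter_um Droplet diameter, um.
#' @return Droplets per minute.
#' @export
droplet_rate <- function(flow_ul_min, diameter_um) {
  check_positive_scalar(flow_ul_min, "flow_ul_min")
  check_positive_scalar(diameter_um, "diameter_um")
  flow_ul_min * UL_TO_UM3 / (pi * diameter_um^3 / 6)
}

#' Rate of cell-bearing droplets
#'
#' The product of the droplet generation rate and the fraction of droplets
#' carrying at least one cell.
#'
#' @param rate Droplets per minute (>= 0).
#' @param occupancy Occupancy fraction in `[0, 1]`.
#' @return Cell-bearing droplets per minute.
#' @export
cell_bearing_rate <- function(rate, occupancy) {
  if (any(rate < 0)) stop_input("`rate` must be >= 0")
  if (any(occupancy < 0) || any(occupancy > 1)) {
    stop_input("`occupancy` must lie in [0, 1]")
  }
  rate * occupancy
}

#' Nominal occupancy rate implied by cell density and droplet size
#'
#' `lambda = c * pi D^3 / 6` with the cell density c in cells/mL
#' (1 mL = 1e12 um^3). In practice the observed lambda is usually lower
#' because cells sediment in the supply tubing before encapsulation.
#'
#' @param cell_density_per_ml Cell density, cells/mL (>= 0).
#' @param diameter_um Droplet diameter, um.
#' @return The nominal lambda.
#' @export
nominal_lambda <- function(cell_density_per_ml, diameter_um) {
  if (cell_density_per_ml < 0) stop_input("`cell_density_per_ml` must be >= 0")
  check_positive_scalar(diameter_um, "diameter_um")
  cell_density_per_ml / ML_TO_UM3 * (pi * diameter_um^3 / 6)
}

#' Cell density after dilution into hydrogel
#'
#' Mixing `v_cells` of suspension at density `c0` with `v_gel` of gel
#' gives `c0 * v_cells / (v_cells + v_gel)`.
#'
#' @param c0 Starting density, cells/mL.
#' @param v_cells Suspension volume (any unit, same as `v_gel`).
#' @param v_gel Gel volume.
#' @return Final density, cells/mL.
#' @export
dilute_density <- function(c0, v_cells, v_gel) {
  if (v_cells < 0 || v_gel < 0) stop_input("volumes must be >= 0")
  if (v_cells + v_gel == 0) stop_input("total volume must be positive")
  c0 * v_cells / (v_cells + v_gel)
}

#' Percent of cells classified as invaded
#'
#' `100 * n_i / (n_b + n_i)`, rounded half-up to the nearest integer for
#' reporting.
#'
#' @param n_i Number of invaded cells.
#' @param n_total Total number of cells (`n_b + n_i`).
#' @return Integer percentage.
#' @export
percent_invaded <- function(n_i, n_total) {
  if (any(n_total <= 0) || any(n_i < 0) || any(n_i > n_total)) {
    stop_input("need 0 <= n_i <= n_total and n_total > 0")
  }
  round_half_up(100 * n_i / n_total)
}

#' Throughput estimate for a loading specification
#'
#' Convenience wrapper combining [droplet_rate()], [occupancy_fraction()]
#' and [cell_bearing_rate()] for a given flow, droplet size and either a
#' lambda or an occupancy fraction.
#'
#' @param flow_ul_min Dispersed-phase flow, uL/min.
#' @param diameter_um Droplet diameter, um.
#' @param occupancy Occupancy fraction; computed from `lambda` if missing.
#' @param lambda Mean cells per droplet (used when `occupancy` is `NULL`).
#' @return A one-row tibble with `droplet_rate_per_min`,
#'   `occupancy_fraction` and `cell_bearing_rate_per_min`.
#' @export
throughput_estimate <- function(flow_ul_min, diameter_um, occupancy = NULL,
                                lambda = NULL) {
  if (is.null(occupancy)) {
    if (is.null(lambda)) stop_input("supply either `occupancy` or `lambda`")
    occupancy <- occupancy_fraction(lambda)
  }
  rate <- droplet_rate(flow_ul_min, diameter_um)
  tibble::tibble(
    droplet_rate_per_min = rate,
    occupancy_fraction = occupancy,
    cell_bearing_rate_per_min = cell_bearing_rate(rate, occupancy)
  )
}
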