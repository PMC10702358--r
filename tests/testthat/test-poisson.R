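test_that("P_k handles the degenerate rate and normalises", {
  expect_equal(poisson_pk(0, 0), 1)
  expect_equal(poisson_pk(0, 1:5), rep(0, 5))
  for (lam in c(0.1, 0.5, 1, 5, 20, 50)) {
    expect_lt(abs(sum(poisson_pk(lam, 0:200)) - 1), 1e-12)
  }
  expect_error(poisson_pk(-1, 0), class = "gelbead_input_error")
  expect_error(poisson_pk(1, -2), class = "gelbead_input_error")
})

test_that("P_1 at lambda = 1 matches a Monte-Carlo frequency", {
  expect_equal(poisson_pk(1, 1), 0.3678794, tolerance = 1e-6)
  freq <- with_seed(11, mean(rpois(1e6, 1) == 1))
  se <- sqrt(0.3678794 * (1 - 0.3678794) / 1e6)
  expect_lt(abs(freq - poisson_pk(1, 1)), 3 * se)
})

test_that("lambda estimation is the arithmetic mean", {
  expect_equal(estimate_lambda(rep(0L, 10)), 0)
  expect_equal(estimate_lambda(c(0L, 1L, 2L)), 1)
  draws <- with_seed(21, rpois(1e4, 0.5))
  expect_lt(abs(estimate_lambda(draws) - 0.5), 3 * sqrt(0.5 / 1e4))
  expect_error(estimate_lambda(integer(0)), class = "gelbead_input_error")
  # data-frame input with k_cells column
  expect_equal(estimate_lambda(tibble::tibble(k_cells = c(0L, 2L))), 1)
})

test_that("binned proportions are closed-form and sum to one", {
  b0 <- binned_proportions(0)
  expect_equal(b0$prop, c(1, 0, 0, 0))
  b1 <- binned_proportions(1)
  expect_equal(b1$prop, c(0.36788, 0.36788, 0.18394, 0.08030), tolerance = 1e-4)
  for (lam in seq(0, 50, by = 2.5)) {
    expect_equal(sum(binned_proportions(lam)$prop), 1, tolerance = 1e-12)
  }
  # P(3+) strictly increases with lambda
  p3 <- vapply(seq(0.1, 10, by = 0.35),
               function(l) binned_proportions(l)$prop[4], numeric(1))
  expect_true(all(diff(p3) > 0))
})

test_that("chi-square gof is zero for exactly proportional data and tracks df", {
  lam <- 0.5
  p <- binned_proportions(lam)$prop
  n <- 2000
  counts <- rep(c(0L, 1L, 2L, 3L), round(n * p))
  g <- goodness_of_fit(counts, lambda = lam)
  expect_lt(g$statistic, 0.05)  # rounding of bin totals only
  expect_gt(g$p_value, 0.99)
  expect_equal(g$df, 3L)
  expect_equal(goodness_of_fit(counts)$df, 2L)
  expect_true(goodness_of_fit(c(0L, 1L, 0L))$small_sample)
})

test_that("gof type-I error is near the nominal 5% level", {
  reject <- with_seed(31, {
    vapply(seq_len(500), function(i) {
      k <- rpois(1e4, 0.3)
      goodness_of_fit(k)$p_value < 0.05
    }, logical(1))
  })
  tol <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(reject) - 0.05), tol)
})

test_that("occupancy fraction and its inverse round trip", {
  expect_equal(occupancy_fraction(0), 0)
  expect_equal(lambda_from_occupancy(0.16), 0.17435, tolerance = 1e-4)
  expect_equal(lambda_from_occupancy(0.27), 0.31471, tolerance = 1e-4)
  lam <- seq(0, 10, by = 0.25)
  expect_lt(max(abs(lambda_from_occupancy(occupancy_fraction(lam)) - lam)), 1e-10)
  expect_error(lambda_from_occupancy(1), class = "gelbead_input_error")
})

test_that("droplet rate arithmetic: volumes, scaling, inverse", {
  expect_equal(droplet_rate(1, 100), 1909.859, tolerance = 1e-4)
  expect_gte(droplet_rate(1, 100), 1800)
  expect_equal(droplet_rate(1, 200), droplet_rate(1, 100) / 8, tolerance = 1e-10)
  expect_equal(droplet_rate(1, 124.0701), 1000, tolerance = 1e-4)
  expect_error(droplet_rate(0, 100), class = "gelbead_input_error")
})

test_that("cell-bearing rates reproduce the 288-486 per minute range", {
  expect_equal(cell_bearing_rate(1800, 0.16), 288)
  expect_equal(cell_bearing_rate(1800, 0.27), 486)
  expect_equal(cell_bearing_rate(1800, 0), 0)
})

test_that("nominal lambda from loading density scales as expected", {
  expect_equal(nominal_lambda(2.5e6, 100), 1.308997, tolerance = 1e-6)
  expect_equal(nominal_lambda(0, 100), 0)
  expect_equal(nominal_lambda(5e6, 100), 2 * nominal_lambda(2.5e6, 100))
  expect_equal(nominal_lambda(2.5e6, 200), 8 * nominal_lambda(2.5e6, 100),
               tolerance = 1e-10)
  # the nominal rate exceeds the lambda implied by the observed 16-27%
  # occupancy: the sedimentation discrepancy, as a property of the numbers
  expect_gt(nominal_lambda(2.5e6, 100), lambda_from_occupancy(0.27))
})

test_that("dilution arithmetic is exact and scale invariant", {
  expect_equal(dilute_density(2.5e7, 15, 135), 2.5e6)
  expect_equal(dilute_density(4e6, 10, 0), 4e6)
  expect_equal(dilute_density(4e6, 7.5, 67.5), dilute_density(4e6, 15, 135))
  expect_error(dilute_density(1e6, 0, 0), class = "gelbead_input_error")
})

test_that("lambda recovery on pure-Poisson synthetic data has <2% bias", {
  counts <- simulate_occupancy(1e5, lambda = 0.3, mode = "poisson", seed = 41)
  lam_hat <- estimate_lambda(counts)
  expect_lt(abs(lam_hat - 0.3) / 0.3, 0.02)
})

test_that("fit_poisson ties the pieces together", {
  counts <- simulate_occupancy(5e3, lambda = 0.4, mode = "poisson", seed = 51)
  fit <- fit_poisson(counts)
  expect_s3_class(fit, "occupancy_fit")
  expect_equal(fit$lambda, mean(counts$k_cells))
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$observed_prop), 1, tolerance = 1e-12)
  expect_equal(sum(td$expected_prop), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$lambda_source, "estimated")
  expect_gt(gl$p_value, 1e-6)  # correctly specified model should fit
})
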