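test_that("droplet video: single monodisperse droplet renders its ring everywhere", {
  sim <- simulate_droplet_video(n_droplets = 1, diameter_cv = 0, noise_sd = 0,
                                seed = 3)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$diameter_um, 100)
  # in every frame the droplet occupies, the darkest pixel sits on the ring
  tr <- sim$truth
  for (t in seq(tr$entry_frame, tr$exit_frame, by = 3)) {
    fr <- sim$frames$frames[[t]]
    cx <- tr$start_x_px + 15 * (t - 1)
    idx <- which(fr == min(fr), arr.ind = TRUE)[1, ]
    d <- sqrt((idx["row"] - tr$center_y_px)^2 + (idx["col"] - cx)^2)
    expect_lt(abs(d - tr$radius_px), 1.2)
  }
})

test_that("the same seed reproduces videos bit for bit", {
  a <- simulate_droplet_video(n_droplets = 3, seed = 9)
  b <- simulate_droplet_video(n_droplets = 3, seed = 9)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth, b$truth)
  c <- simulate_droplet_video(n_droplets = 3, seed = 10)
  expect_false(identical(a$frames$frames, c$frames$frames))
})

test_that("true diameters follow the requested mean and CV", {
  sim <- simulate_droplet_video(n_droplets = 200, diameter_mean_um = 100,
                                diameter_cv = 0.03, seed = 12)
  d <- sim$truth$diameter_um
  expect_lt(abs(mean(d) - 100), 3 * 100 * 0.03 / sqrt(200))
  expect_lt(abs(sd(d) / mean(d) - 0.03), 0.01)
})

test_that("a droplet larger than the frame is rejected", {
  expect_error(
    simulate_droplet_video(n_droplets = 1, diameter_mean_um = 400,
                           frame_width = 128, frame_height = 64,
                           pixel_size_um = 1, seed = 1),
    class = "gelbead_input_error"
  )
})

test_that("occupancy generator: lambda 0 gives all zeros; seeds reproduce", {
  z <- simulate_occupancy(500, lambda = 0, seed = 4)
  expect_true(all(z$k_cells == 0L))
  a <- simulate_occupancy(1000, lambda = 0.4, seed = 5)
  b <- simulate_occupancy(1000, lambda = 0.4, seed = 5)
  expect_identical(a$k_cells, b$k_cells)
})

test_that("pure-mode binned proportions match the closed form within 3 SE", {
  n <- 1e5
  sim <- simulate_occupancy(n, lambda = 0.3, mode = "poisson", seed = 6)
  obs <- bin_occupancy(sim)
  expd <- binned_proportions(0.3)
  for (i in 1:4) {
    se <- sqrt(expd$prop[i] * (1 - expd$prop[i]) / n)
    expect_lt(abs(obs$prop[i] - expd$prop[i]), 3 * se + 1e-9)
  }
})

test_that("aggregation shifts mass from singletons into the 3+ bin at fixed mean", {
  n <- 1e5
  lam <- 0.3
  p_agg <- 0.5
  agg <- simulate_occupancy(n, lambda = lam, mode = "aggregated",
                            p_agg = p_agg, seed = 7)
  # empirical mean matches the matched-mean construction
  expect_lt(abs(mean(agg$k_cells) - lam), 3 * sqrt(2 * lam / n) + 0.01)
  obs <- bin_occupancy(agg)
  pois <- binned_proportions(lam)
  # analytic compound-Poisson pmf as the oracle
  pmf <- compound_pois_geom_pmf(lam * (1 - p_agg), p_agg, kmax = 60)
  ana <- c(pmf[1:3], 1 - sum(pmf[1:3]))
  expect_gt(ana[4], pois$prop[4])          # the aggregation signature
  expect_lt(ana[2], pois$prop[2])
  for (i in 1:4) {
    expect_lt(abs(obs$prop[i] - ana[i]), 4 * sqrt(ana[i] * (1 - ana[i]) / n) + 1e-9)
  }
  # and the empirical 3+ excess is visible directly
  expect_gt(obs$prop[4], pois$prop[4])
  expect_lt(obs$prop[2], pois$prop[2])
})

test_that("a single rendered nucleus has the right voxel volume", {
  sim <- simulate_confocal_stack(n_inside = 1, n_invaded = 0,
                                 bead_radius_um = 20,
                                 nucleus_radius_mean_um = 5,
                                 nucleus_radius_sd_um = 0,
                                 spacing = c(dz = 1, dy = 1, dx = 1),
                                 blur_sigma_um = c(x = 0, y = 0, z = 0),
                                 noise_sd = 0, seed = 8)
  vox <- sim$stack$voxels
  n_fg <- sum(vox > 0.5)
  expect_lt(abs(n_fg - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.05)
  lab <- gelbead:::cpp_label3d(as.integer(vox > 0.5), dim(vox), 26L)
  expect_equal(max(lab), 1L)
})

test_that("invaded distances at or below the nucleus radius are rejected", {
  expect_error(
    simulate_confocal_stack(n_inside = 2, n_invaded = 2,
                            invasion_distances_um = c(0, 0), seed = 9),
    "invasion distances"
  )
})

test_that("requested counts and distances appear in the truth table exactly", {
  sim <- simulate_confocal_stack(n_inside = 6, n_invaded = 3,
                                 invasion_distances_um = c(15, 25, 40),
                                 bead_radius_um = 30, seed = 10,
                                 spacing = c(dz = 2, dy = 1, dx = 1))
  expect_equal(sum(!sim$truth$invaded), 6L)
  expect_equal(sum(sim$truth$invaded), 3L)
  expect_equal(sort(sim$truth$surface_distance_um[sim$truth$invaded]),
               c(15, 25, 40), tolerance = 1e-9)
  expect_true(all(sim$truth$surface_distance_um[!sim$truth$invaded] == 0))
})

test_that("generator outputs round trip through the package readers", {
  tmp <- tempfile("roundtrip")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  # frames -> multi-page TIFF -> frame_sequence
  vid <- simulate_droplet_video(n_droplets = 2, seed = 11,
                                diameter_mean_um = 60,
                                frame_width = 96, frame_height = 48)
  f <- file.path(tmp, "video.tiff")
  write_frame_sequence(vid$frames, f)
  back <- read_frame_sequence(f, pixel_size = 2, fps = 30)
  expect_equal(length(back), length(vid$frames))
  expect_lt(max(abs(back$frames[[3]] - vid$frames$frames[[3]])), 1 / 65535 + 1e-6)
  # occupancy -> CSV -> reader
  occ <- simulate_occupancy(50, lambda = 0.5, seed = 12)
  oc <- file.path(tmp, "occ.csv")
  utils::write.csv(occ, oc, row.names = FALSE)
  expect_equal(read_occupancy_csv(oc)$k_cells, occ$k_cells)
  # stack -> TIFF -> confocal_stack
  sc <- simulate_confocal_stack(n_inside = 3, n_invaded = 0,
                                bead_radius_um = 15, seed = 13,
                                spacing = c(dz = 2, dy = 1, dx = 1))
  sf <- file.path(tmp, "stack.tiff")
  write_stack_tiff(sc$stack, sf)
  rb <- read_stack_tiff(sf, spacing = c(dz = 2, dy = 1, dx = 1))
  expect_equal(dim(rb), dim(sc$stack))
  clipped <- pmin(pmax(sc$stack$voxels, 0), 1)
  expect_lt(max(abs(rb$voxels - clipped)), 1 / 65535 + 1e-6)
})
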