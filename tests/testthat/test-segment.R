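# deterministic sphere layouts rendered by the independent helper
iso_spacing <- c(dz = 1, dy = 1, dx = 1)

test_that("ten well-separated spheres are segmented exactly", {
  centers <- with_seed(13, {
    pts <- matrix(NA_real_, 10, 3)
    i <- 1
    while (i <= 10) {
      p <- runif(3, 10, 50)
      if (i == 1 || all(sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                                        matrix(p, i - 1, 3, byrow = TRUE))^2)) > 13)) {
        pts[i, ] <- p
        i <- i + 1
      }
    }
    pts
  })
  arr <- render_spheres(centers, rep(4, 10), c(60, 60, 60), iso_spacing)
  arr <- arr + with_seed(14, array(rnorm(length(arr), 0, 0.02), dim(arr)))
  st <- confocal_stack(arr, iso_spacing)
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.8))
  expect_equal(nrow(seg$regions), 10L)
  got <- as.matrix(seg$regions[order(seg$regions$x_um), c("x_um", "y_um", "z_um")])
  want <- centers[order(centers[, 1]), , drop = FALSE]
  expect_lt(max(abs(got - want)), sqrt(3))  # within one voxel diagonal
  # sphere-equivalent radius identity r = (3V / 4 pi)^(1/3)
  expect_equal(seg$regions$radius_um,
               (3 * seg$regions$volume_um3 / (4 * pi))^(1 / 3),
               tolerance = 1e-9)
})

test_that("a blank stack yields zero regions, not an error", {
  st <- confocal_stack(array(0, c(20, 20, 10)), iso_spacing)
  seg <- segment_nuclei(st)
  expect_equal(nrow(seg$regions), 0L)
})

test_that("two spheres overlapping by a quarter radius are separated", {
  r <- 5
  centers <- rbind(c(20, 20, 15), c(20 + 1.75 * r, 20, 15))
  arr <- render_spheres(centers, c(r, r), c(40, 48, 30), iso_spacing)
  st <- confocal_stack(arr, iso_spacing)
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.5,
                                                seed_min_distance = 6))
  expect_equal(nrow(seg$regions), 2L)
  got <- sort(seg$regions$x_um)
  expect_lt(abs(got[1] - 20), sqrt(3))
  expect_lt(abs(got[2] - (20 + 1.75 * r)), sqrt(3))
})

test_that("anisotropic stacks segment after automatic z inflation", {
  sp <- c(dz = 4, dy = 1, dx = 1)
  centers <- rbind(c(15, 15, 16), c(32, 30, 24))
  arr <- render_spheres(centers, c(4, 4), c(45, 45, 11), sp)
  st <- confocal_stack(arr, sp)
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.8))
  expect_equal(seg$z_inflation, 3L)
  expect_equal(nrow(seg$regions), 2L)
  got <- as.matrix(seg$regions[order(seg$regions$x_um), c("x_um", "y_um", "z_um")])
  expect_lt(max(abs(got - centers)), sqrt(1 + 1 + 4^2))
})

test_that("a fused pair passing the 2x rule is split back to its two centres", {
  # four singletons (r = 4) set the average; a fused pair of larger
  # spheres (r = 4.68, centres 1.6 r apart) lands between 2x and 2.5x the
  # average, so m = round(V / average) = 2
  r_big <- 4.68
  sep <- 1.6 * r_big
  centers <- rbind(
    c(14, 14, 12), c(38, 14, 12), c(14, 38, 12), c(38, 38, 12),
    c(22, 26, 26), c(22 + sep, 26, 26)
  )
  arr <- render_spheres(centers, c(4, 4, 4, 4, r_big, r_big),
                        c(52, 54, 40), iso_spacing)
  st <- confocal_stack(arr, iso_spacing)
  # a wide seed suppression merges the close pair into one region
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.5,
                                                seed_min_distance = 9))
  expect_equal(nrow(seg$regions), 5L)
  fused_vox <- max(seg$regions$n_voxels)
  expect_gt(max(seg$regions$volume_um3), 2 * mean(seg$regions$volume_um3))
  # with the seed separation relaxed, splitting re-runs the watershed
  # inside the region from its two strongest distance-map maxima
  seg$params$seed_min_distance <- 5
  split <- split_oversized(seg)
  expect_equal(nrow(split$regions), 6L)
  expect_equal(sum(split$regions$n_voxels), sum(seg$regions$n_voxels))
  sub <- split$regions[abs(split$regions$y_um - 26) < 3 &
                         abs(split$regions$z_um - 26) < 3, ]
  expect_equal(nrow(sub), 2L)
  expect_equal(sum(sub$n_voxels), fused_vox)
  got <- sort(sub$x_um)
  expect_lt(abs(got[1] - 22), sqrt(3))
  expect_lt(abs(got[2] - (22 + sep)), sqrt(3))
})

test_that("regions below the split threshold are left unchanged", {
  centers <- rbind(c(12, 12, 10), c(30, 12, 10), c(21, 30, 20))
  arr <- render_spheres(centers, c(4, 4, 4), c(42, 42, 30), iso_spacing)
  st <- confocal_stack(arr, iso_spacing)
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.5))
  expect_equal(nrow(seg$regions), 3L)
  split <- split_oversized(seg)
  expect_identical(split$labels, seg$labels)
  expect_equal(split$regions, seg$regions)
})

test_that("principal-axis bisection splits a fused row when maxima are scarce", {
  # three spheres in a row fuse into one region; its two kept maxima are
  # closer than the seed separation, so the fallback divides the voxels
  # by 1D k-means along the principal axis into round(V / average) parts
  centers <- rbind(
    c(8, 8, 8), c(36, 8, 8),
    c(16, 30, 20), c(22.4, 30, 20), c(28.8, 30, 20)
  )
  arr <- render_spheres(centers, c(2.8, 2.8, 4, 4, 4), c(46, 44, 30),
                        iso_spacing)
  st <- confocal_stack(arr, iso_spacing)
  seg <- segment_nuclei(st, segmentation_params(smooth_sigma = 0.4,
                                                seed_min_distance = 14))
  expect_equal(nrow(seg$regions), 3L)
  vols <- seg$regions$volume_um3
  expect_gt(max(vols), 2 * mean(vols))
  m_expected <- as.integer(round(max(vols) / mean(vols)))
  split <- split_oversized(seg)
  expect_equal(nrow(split$regions), 2L + m_expected)
  expect_equal(sum(split$regions$n_voxels), sum(seg$regions$n_voxels))
})

test_that("rotating a stack 90 degrees about z leaves the metrics unchanged", {
  sim <- simulate_confocal_stack(n_inside = 10, n_invaded = 4,
                                 invasion_distances_um = c(12, 18, 25, 30),
                                 bead_radius_um = 25, seed = 17,
                                 spacing = c(dz = 2, dy = 1, dx = 1))
  rep1 <- quantify_invasion(sim$stack, bead_radius_um = 25)
  vox <- sim$stack$voxels
  rot <- aperm(vox, c(2, 1, 3))[, dim(vox)[1]:1, , drop = FALSE]
  st_rot <- confocal_stack(rot, sim$stack$spacing)
  rep2 <- quantify_invasion(st_rot, bead_radius_um = 25)
  expect_equal(rep2$n_b, rep1$n_b)
  expect_equal(rep2$n_i, rep1$n_i)
  # watershed tie-breaks at label boundaries may shift centroids by a
  # fraction of a voxel under the rotation
  expect_equal(rep2$d_max_um, rep1$d_max_um, tolerance = 0.02)
})
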