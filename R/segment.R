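#' Parameters for 3D nucleus segmentation
#'
#' @param z_inflation Integer number of interpolated planes inserted per
#'   z-gap before segmentation, or `NULL` to choose automatically so the
#'   inflated z-spacing comes closest to the x-y spacing
#'   (`ceiling(dz / dx) - 1`).
#' @param smooth_sigma Gaussian smoothing width in micrometres, isotropic
#'   in physical units (default 1 um).
#' @param threshold Manual intensity threshold overriding Otsu's method,
#'   or `NULL` (default) for a global Otsu threshold on the smoothed
#'   stack.
#' @param seed_min_distance Minimum separation between watershed seeds in
#'   micrometres (default 6 um, about one nucleus diameter).
#' @param split_factor A region is split when its volume exceeds
#'   `split_factor` times the average region volume (default 2).
#' @param connectivity Voxel neighbourhood, 6 or 26 (default 26).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(z_inflation = NULL, smooth_sigma = 1.0,
                                threshold = NULL, seed_min_distance = 6,
                                split_factor = 2.0, connectivity = 26L) {
  if (!is.null(z_inflation) &&
      (z_inflation < 0 || z_inflation != floor(z_inflation))) {
    stop_input("`z_inflation` must be NULL or a non-negative integer")
  }
  if (smooth_sigma < 0) stop_input("`smooth_sigma` must be >= 0")
  if (split_factor <= 1) stop_input("`split_factor` must be > 1")
  if (!connectivity %in% c(6L, 26L)) stop_input("`connectivity` must be 6 or 26")
  structure(
    list(
      z_inflation = z_inflation,
      smooth_sigma = smooth_sigma,
      threshold = threshold,
      seed_min_distance = seed_min_distance,
      split_factor = split_factor,
      connectivity = as.integer(connectivity)
    ),
    class = "segmentation_params"
  )
}

# spacing per array dimension [y, x, z]
spacing_arr <- function(spacing) unname(spacing[c("dy", "dx", "dz")])

# physical centroids/volumes of labelled voxels
region_table <- function(labels, dims, spacing) {
  fg <- which(labels > 0L)
  if (length(fg) == 0L) {
    return(tibble::tibble(
      label = integer(), x_um = numeric(), y_um = numeric(), z_um = numeric(),
      n_voxels = integer(), volume_um3 = numeric(), radius_um = numeric()
    ))
  }
  lab <- labels[fg]
  co <- arrayInd(fg, dims)
  y <- (co[, 1] - 1) * spacing["dy"]
  x <- (co[, 2] - 1) * spacing["dx"]
  z <- (co[, 3] - 1) * spacing["dz"]
  n <- as.integer(table(lab))
  ids <- as.integer(names(table(lab)))
  voxvol <- prod(spacing)
  sums <- rowsum(cbind(x, y, z), lab)
  vol <- n * voxvol
  tibble::tibble(
    label = ids,
    x_um = sums[, 1] / n,
    y_um = sums[, 2] / n,
    z_um = sums[, 3] / n,
    n_voxels = n,
    volume_um3 = vol,
    radius_um = (3 * vol / (4 * pi))^(1 / 3)
  )
}

# greedy minimum-distance suppression of seed candidates, strongest first
suppress_seeds <- function(coords_um, strength, min_dist) {
  ord <- order(-strength, seq_along(strength))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L) {
      kept <- i
      next
    }
    d2 <- (coords_um[kept, 1] - coords_um[i, 1])^2 +
      (coords_um[kept, 2] - coords_um[i, 2])^2 +
      (coords_um[kept, 3] - coords_um[i, 3])^2
    if (all(d2 >= min_dist^2)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Segment nuclei in a 3D confocal stack
#'
#' The watershed pipeline for stained-nuclei stacks: (1) z-resolution
#' inflation by linear interpolation ([interpolate_z()]); (2) Gaussian
#' smoothing, isotropic in physical units; (3) global Otsu thresholding
#' into a foreground mask; (4) exact anisotropic Euclidean distance
#' transform of the mask in micrometres; (5) marker-controlled watershed
#' on the negated distance map, seeded at distance-map local maxima at
#' least `seed_min_distance` apart (ties broken by distance value then
#' scan order, for determinism). Region centroids and volumes are
#' reported in physical micrometres, voxel-centre convention with the
#' origin at the first voxel's centre; each region's radius comes from
#' the volume of an equivalent sphere, `V = 4/3 pi r^3`.
#'
#' @param stack A [confocal_stack()].
#' @param params A [segmentation_params()] list.
#' @return A `nucleus_segmentation` object: `regions` (tibble with
#'   `label`, `x_um`, `y_um`, `z_um`, `n_voxels`, `volume_um3`,
#'   `radius_um`), the label array, the distance map, spacing/dims of the
#'   processed stack, and the threshold used. An empty-foreground stack
#'   yields zero regions, not an error.
#' @export
segment_nuclei <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "confocal_stack"))
  zi <- params$z_inflation
  if (is.null(zi)) {
    zi <- max(0L, as.integer(ceiling(stack$spacing["dz"] / stack$spacing["dx"])) - 1L)
  }
  if (zi > 0L) stack <- interpolate_z(stack, zi)
  sp <- stack$spacing
  dims <- dim(stack$voxels)
  arr <- stack$voxels
  if (params$smooth_sigma > 0) {
    sig_vox <- params$smooth_sigma / c(sp["dy"], sp["dx"], sp["dz"])
    arr <- gaussian_smooth_3d(arr, sig_vox)
  }
  thr <- params$threshold %||% otsu_threshold(arr)
  mask <- as.integer(arr > thr)
  res <- structure(
    list(
      regions = region_table(array(0L, dims), dims, sp),
      labels = array(0L, dims),
      distance_map = NULL,
      spacing = sp,
      dims = dims,
      threshold = thr,
      z_inflation = zi,
      params = params
    ),
    class = "nucleus_segmentation"
  )
  if (sum(mask) == 0L) return(res)  # "no nuclei detected"
  edt <- cpp_edt3d(mask, dims, spacing_arr(sp))
  cand <- cpp_local_maxima3d(edt, mask, dims, params$connectivity)
  co <- arrayInd(cand, dims)
  cand_um <- cbind(
    (co[, 2] - 1) * sp["dx"],
    (co[, 1] - 1) * sp["dy"],
    (co[, 3] - 1) * sp["dz"]
  )
  kept <- suppress_seeds(cand_um, edt[cand], params$seed_min_distance)
  markers <- integer(prod(dims))
  markers[cand[kept]] <- seq_along(kept)
  labels <- cpp_watershed3d(-edt, markers, mask, dims, params$connectivity)
  labels <- array(labels, dims)
  res$labels <- labels
  res$distance_map <- array(edt, dims)
  res$regions <- region_table(labels, dims, sp)
  res
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf(
    "<nucleus_segmentation> %d regions in a %s stack (threshold %.4g)\n",
    nrow(x$regions), paste(x$dims, collapse = " x "), x$threshold
  ))
  invisible(x)
}

#' Split regions much larger than the average
#'
#' A fused clump of nuclei shows up as one region far larger than its
#' peers. Any region whose volume exceeds `split_factor` times the
#' average region volume is split into `m = round(V / average)` parts
#' (at least 2) by re-running the marker-controlled watershed inside the
#' region, seeded at its `m` strongest distance-map maxima (maxima closer
#' than `seed_min_distance` count once). If fewer than `m` distinct
#' maxima exist, voxels are divided by 1D k-means on their projection
#' onto the region's principal axis. A single pass is made — sub-regions
#' are not re-examined — and sub-region voxel counts always sum to the
#' parent's.
#'
#' @param seg A `nucleus_segmentation` from [segment_nuclei()].
#' @param split_factor Overrides the factor stored in the segmentation
#'   parameters (default: use stored value).
#' @return The updated `nucleus_segmentation`.
#' @export
split_oversized <- function(seg, split_factor = NULL) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  split_factor <- split_factor %||% seg$params$split_factor
  regions <- seg$regions
  if (nrow(regions) == 0L) return(seg)
  avg <- mean(regions$volume_um3)
  over <- regions$label[regions$volume_um3 > split_factor * avg]
  if (length(over) == 0L) return(seg)
  labels <- seg$labels
  dims <- seg$dims
  sp <- seg$spacing
  edt <- seg$distance_map
  next_label <- max(regions$label) + 1L
  for (lb in over) {
    vol <- regions$volume_um3[regions$label == lb]
    m <- max(2L, as.integer(round_half_up(vol / avg)))
    reg_mask <- as.integer(labels == lb)
    sub <- NULL
    if (!is.null(edt)) {
      cand <- cpp_local_maxima3d(as.numeric(edt), reg_mask, dims,
                                 seg$params$connectivity)
      if (length(cand) > 0L) {
        co <- arrayInd(cand, dims)
        cand_um <- cbind(
          (co[, 2] - 1) * sp["dx"],
          (co[, 1] - 1) * sp["dy"],
          (co[, 3] - 1) * sp["dz"]
        )
        kept <- suppress_seeds(cand_um, edt[cand], seg$params$seed_min_distance)
        if (length(kept) > m) {
          # m strongest of the distinct maxima
          kept <- kept[order(-edt[cand[kept]], kept)][seq_len(m)]
        }
        if (length(kept) == m) {
          markers <- integer(prod(dims))
          markers[cand[kept]] <- seq_len(m)
          sub <- cpp_watershed3d(-as.numeric(edt), markers, reg_mask, dims,
                                 seg$params$connectivity)
        }
      }
    }
    if (is.null(sub)) {
      # principal-axis fallback: 1D k-means on the PC1 projection with
      # deterministic quantile-spaced initial centres
      vox <- which(reg_mask == 1L)
      co <- arrayInd(vox, dims)
      pts <- cbind(
        (co[, 2] - 1) * sp["dx"],
        (co[, 1] - 1) * sp["dy"],
        (co[, 3] - 1) * sp["dz"]
      )
      pc1 <- prcomp(pts, center = TRUE, scale. = FALSE)$x[, 1]
      centers <- quantile(pc1, probs = (seq_len(m) - 0.5) / m, names = FALSE)
      km <- kmeans(pc1, centers = matrix(centers, ncol = 1))
      sub <- integer(prod(dims))
      sub[vox] <- km$cluster
    }
    idx <- which(sub > 0L)
    relab <- c(lb, seq.int(next_label, length.out = max(sub) - 1L))
    labels[idx] <- relab[sub[idx]]
    next_label <- next_label + max(sub) - 1L
  }
  seg$labels <- labels
  seg$regions <- region_table(labels, dims, sp)
  seg
}

#' Estimate the Matrigel bead position
#'
#' The bead centre is the unweighted mean of the nucleus centroids; its
#' radius is supplied (default 50 um, half the 100 um target droplet
#' diameter) since the droplet-sizing step, not the confocal stack, is
#' where the bead size is measured. Note the estimator is biased towards
#' invaded cells by about `(n_i / n) *` mean displacement.
#'
#' @param x A `nucleus_segmentation` or a regions tibble with
#'   `x_um`, `y_um`, `z_um` columns.
#' @param radius_um Bead radius in micrometres (default 50).
#' @return A `bead_model` with `center` (named x/y/z, um) and
#'   `radius_um`.
#' @export
estimate_bead <- function(x, radius_um = 50) {
  regions <- if (inherits(x, "nucleus_segmentation")) x$regions else x
  if (nrow(regions) == 0L) stop_input("cannot estimate a bead from zero regions")
  check_positive_scalar(radius_um, "radius_um")
  structure(
    list(
      center = c(
        x = mean(regions$x_um),
        y = mean(regions$y_um),
        z = mean(regions$z_um)
      ),
      radius_um = radius_um
    ),
    class = "bead_model"
  )
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf(
    "<bead_model> center (%.1f, %.1f, %.1f) um, R = %.1f um\n",
    x$center["x"], x$center["y"], x$center["z"], x$radius_um
  ))
  invisible(x)
}

#' Classify nuclei as bead-resident or invaded
#'
#' For each nucleus the distance from the bead surface is
#' `max(0, ||centroid - center|| - R)`; a cell counts as invaded when
#' that distance exceeds its own sphere-equivalent radius. Reports the
#' resident count `n_b`, invaded count `n_i`, the maximum invasion
#' distance `d_max` (0 when nothing invaded) and the percent invaded
#' (`100 n_i / (n_b + n_i)`, integer-rounded for reporting, full
#' precision retained). The centre-referenced distance is also kept for
#' transparency.
#'
#' @param x A `nucleus_segmentation` or regions tibble (needs `x_um`,
#'   `y_um`, `z_um`, `radius_um`).
#' @param bead A `bead_model` from [estimate_bead()].
#' @return An `invasion_report` with a per-cell tibble and the summary
#'   metrics; see [tidy.invasion_report()] and
#'   [glance.invasion_report()].
#' @export
classify_invasion <- function(x, bead) {
  stopifnot(inherits(bead, "bead_model"))
  regions <- if (inherits(x, "nucleus_segmentation")) x$regions else x
  cells <- dplyr::mutate(
    regions,
    center_distance_um = sqrt(
      (.data$x_um - bead$center["x"])^2 +
        (.data$y_um - bead$center["y"])^2 +
        (.data$z_um - bead$center["z"])^2
    ),
    surface_distance_um = pmax(0, .data$center_distance_um - bead$radius_um),
    invaded = .data$surface_distance_um > .data$radius_um
  )
  n_i <- sum(cells$invaded)
  n_b <- nrow(cells) - n_i
  structure(
    list(
      cells = cells,
      bead = bead,
      n_b = n_b,
      n_i = n_i,
      d_max_um = if (n_i > 0) max(cells$surface_distance_um[cells$invaded]) else 0,
      percent_invaded = if (nrow(cells) > 0) 100 * n_i / nrow(cells) else NA_real_,
      percent_invaded_reported = if (nrow(cells) > 0) {
        as.integer(round_half_up(100 * n_i / nrow(cells)))
      } else {
        NA_integer_
      }
    ),
    class = "invasion_report"
  )
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf(
    "<invasion_report> n_b = %d, n_i = %d (%d%% invaded), d_max = %.1f um\n",
    x$n_b, x$n_i, x$percent_invaded_reported, x$d_max_um
  ))
  invisible(x)
}

#' Run the full invasion quantification pipeline on a stack
#'
#' Convenience wrapper: [segment_nuclei()], [split_oversized()],
#' [estimate_bead()] and [classify_invasion()] in sequence.
#'
#' @param stack A [confocal_stack()].
#' @param bead_radius_um Bead radius in micrometres.
#' @param params A [segmentation_params()] list.
#' @return An `invasion_report`.
#' @export
quantify_invasion <- function(stack, bead_radius_um = 50,
                              params = segmentation_params()) {
  seg <- segment_nuclei(stack, params)
  seg <- split_oversized(seg)
  if (nrow(seg$regions) == 0L) {
    stop_input("no nuclei detected; cannot quantify invasion")
  }
  bead <- estimate_bead(seg, radius_um = bead_radius_um)
  rep <- classify_invasion(seg, bead)
  rep$segmentation <- seg
  rep
}
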