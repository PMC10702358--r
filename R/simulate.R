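# Seeded synthetic-data generators with ground truth for every pipeline
# stage. Defaults emulate the study conditions: ~100 um monodisperse
# droplets filmed at 30 fps, Poisson cell loading with an optional
# aggregation excess, and confocal stacks of ~60-110 spherical nuclei
# clustered in a ~100 um bead with a minority displaced 10-70 um outward.

#' Simulate a bright-field video of droplets traversing a channel
#'
#' Renders droplets as dark rings on a mid-gray background, translating
#' at constant speed left to right through the frame in a regularly
#' spaced train, plus Gaussian pixel noise. Per-droplet true diameters
#' are drawn from a normal distribution with the requested coefficient of
#' variation. Deterministic under a fixed seed.
#'
#' @param n_droplets Number of droplets in the train.
#' @param diameter_mean_um Mean droplet diameter, um.
#' @param diameter_cv Coefficient of variation of the diameter (fraction).
#' @param speed_px Droplet speed in pixels per frame.
#' @param frame_width,frame_height Frame size in pixels.
#' @param pixel_size_um Pixel size, um/px.
#' @param fps Frame rate, frames/s.
#' @param spacing_px Centre-to-centre droplet spacing in the train;
#'   default 1.3 times the largest diameter.
#' @param ring_contrast Depth of the dark ring below the background level.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed Integer RNG seed.
#' @return A list with `frames` (a [frame_sequence()]) and `truth`, a
#'   tibble with per-droplet `droplet_id`, `diameter_um`, `radius_px`,
#'   `center_y_px`, `start_x_px`, `entry_frame`, `exit_frame`.
#' @export
simulate_droplet_video <- function(n_droplets = 200, diameter_mean_um = 100,
                                   diameter_cv = 0.03, speed_px = 15,
                                   frame_width = 256L, frame_height = 96L,
                                   pixel_size_um = 2, fps = 30,
                                   spacing_px = NULL, ring_contrast = 0.35,
                                   noise_sd = 0.02, seed = 1L) {
  check_positive_scalar(diameter_mean_um, "diameter_mean_um")
  check_positive_scalar(speed_px, "speed_px")
  if (diameter_cv < 0) stop_input("`diameter_cv` must be >= 0")
  with_seed(seed, {
    d_px_mean <- diameter_mean_um / pixel_size_um
    d_px <- rnorm(n_droplets, d_px_mean, diameter_cv * d_px_mean)
    d_px <- pmax(d_px, 6)
    r_px <- d_px / 2
    if (max(d_px) + 6 >= min(frame_width, frame_height)) {
      stop_input("droplet larger than the frame: enlarge the frame or shrink the droplets")
    }
    if (is.null(spacing_px)) spacing_px <- 1.3 * max(d_px)
    cy <- frame_height / 2 + runif(n_droplets, -2, 2)
    x0 <- 1 - r_px - (seq_len(n_droplets) - 1) * spacing_px
    # frame t (1-based): center x = x0 + speed_px * (t - 1)
    entry <- pmax(1L, as.integer(ceiling((1 - x0) / speed_px)) + 1L)
    exit <- as.integer(floor((frame_width - x0) / speed_px)) + 1L
    n_frames <- as.integer(ceiling((frame_width + r_px[n_droplets] - x0[n_droplets]) /
                                     speed_px)) + 1L
    rows <- seq_len(frame_height)
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      img <- matrix(0.5, frame_height, frame_width)
      cx <- x0 + speed_px * (t - 1)
      vis <- which(cx > -r_px - 3 & cx < frame_width + r_px + 3)
      for (i in vis) {
        c1 <- max(1L, floor(cx[i] - r_px[i] - 3))
        c2 <- min(frame_width, ceiling(cx[i] + r_px[i] + 3))
        if (c1 > c2) next
        r1 <- max(1L, floor(cy[i] - r_px[i] - 3))
        r2 <- min(frame_height, ceiling(cy[i] + r_px[i] + 3))
        dd <- sqrt(outer((r1:r2 - cy[i])^2, (c1:c2 - cx[i])^2, "+"))
        img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] -
          ring_contrast * exp(-0.5 * (dd - r_px[i])^2)
      }
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, noise_sd),
                            frame_height, frame_width)
      }
      frames[[t]] <- pmin(pmax(img, 0), 1)
    }
    list(
      frames = frame_sequence(frames, pixel_size = pixel_size_um, fps = fps),
      truth = tibble::tibble(
        droplet_id = seq_len(n_droplets),
        diameter_um = d_px * pixel_size_um,
        radius_px = r_px,
        center_y_px = cy,
        start_x_px = x0,
        entry_frame = entry,
        exit_frame = exit
      )
    )
  })
}

#' Simulate per-droplet cell counts
#'
#' `mode = "poisson"` draws counts from a Poisson distribution with mean
#' `lambda` — the ideal of independent cell arrivals. `mode =
#' "aggregated"` emulates cell clumping in the suspension before
#' encapsulation with a compound Poisson: the number of clusters per
#' droplet is Poisson(`lambda_clusters`) and each cluster carries a
#' geometric number of cells with `P(size = s) = (1 - p_agg) p_agg^(s-1)`
#' (mean `1 / (1 - p_agg)`). When `lambda_clusters` is `NULL` it is set
#' to `lambda * (1 - p_agg)` so the overall mean matches `lambda`;
#' aggregation then shifts mass from the singleton bin into the 3+ bin at
#' fixed mean.
#'
#' @param n_droplets Number of droplets.
#' @param lambda Target mean cells per droplet.
#' @param mode `"poisson"` or `"aggregated"`.
#' @param p_agg Aggregation strength in `[0, 1)`; 0 reduces to pure
#'   Poisson.
#' @param lambda_clusters Mean clusters per droplet (aggregated mode);
#'   overrides the matched-mean default.
#' @param seed Integer RNG seed.
#' @return A tibble with `droplet_id` and `k_cells`; generator settings
#'   are attached as attributes.
#' @export
simulate_occupancy <- function(n_droplets, lambda = 0.3,
                               mode = c("poisson", "aggregated"),
                               p_agg = 0.5, lambda_clusters = NULL,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (lambda < 0) stop_input("`lambda` must be >= 0")
  if (p_agg < 0 || p_agg >= 1) stop_input("`p_agg` must lie in [0, 1)")
  with_seed(seed, {
    if (mode == "poisson") {
      k <- rpois(n_droplets, lambda)
    } else {
      lc <- lambda_clusters %||% (lambda * (1 - p_agg))
      ncl <- rpois(n_droplets, lc)
      k <- integer(n_droplets)
      pos <- which(ncl > 0)
      if (length(pos) > 0L) {
        sizes <- 1L + rgeom(sum(ncl[pos]), prob = 1 - p_agg)
        k[pos] <- as.integer(rowsum(sizes, rep.int(seq_along(pos), ncl[pos])))
      }
      lambda_clusters <- lc
    }
    out <- tibble::tibble(droplet_id = seq_len(n_droplets), k_cells = as.integer(k))
    attr(out, "mode") <- mode
    attr(out, "lambda") <- lambda
    attr(out, "p_agg") <- if (mode == "aggregated") p_agg else NA_real_
    attr(out, "lambda_clusters") <- if (mode == "aggregated") lambda_clusters else NA_real_
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a 3D confocal stack of nuclei in and around a Matrigel bead
#'
#' Places `n_inside` nucleus centres uniformly inside the bead sphere
#' (rejection sampling under a minimum-separation constraint) and
#' `n_invaded` centres at the given distances from the bead surface in
#' uniformly random directions, renders every nucleus as an anti-aliased
#' uniform-intensity sphere on an anisotropic voxel grid, then applies
#' anisotropic Gaussian blur and additive Gaussian noise (optional
#' Poisson shot noise). Deterministic under a fixed seed.
#'
#' @param n_inside Number of bead-resident nuclei.
#' @param n_invaded Number of invaded nuclei.
#' @param invasion_distances_um Either a vector of length `n_invaded`
#'   with the surface distances of the invaded cells, or a length-2 range
#'   they are drawn from uniformly (default `c(10, 70)`). All distances
#'   must exceed the largest nucleus radius.
#' @param bead_radius_um Bead radius, um (default 50, half the 100 um
#'   target droplet diameter).
#' @param nucleus_radius_mean_um,nucleus_radius_sd_um Normal parameters
#'   of the nucleus radius, um.
#' @param spacing Voxel spacing, named `c(dz=, dy=, dx=)` um (default
#'   4/1/1: x-y resolution much finer than z, as in a confocal stack).
#' @param blur_sigma_um Anisotropic PSF blur, named `c(x=, y=, z=)` um.
#' @param noise_sd Additive Gaussian noise SD.
#' @param shot_noise_scale Optional photon count at unit intensity; when
#'   set, Poisson shot noise is applied at that scale.
#' @param min_separation_um Minimum centre-to-centre nucleus distance.
#' @param margin_um Empty margin around the furthest possible nucleus.
#' @param seed Integer RNG seed.
#' @param max_tries Rejection-sampling attempts per nucleus before the
#'   packing is declared infeasible.
#' @return A list with `stack` (a [confocal_stack()]), `truth` (tibble
#'   with `cell_id`, `x_um`, `y_um`, `z_um`, `radius_um`, `invaded`,
#'   `surface_distance_um`) and `bead` (the true bead model).
#' @export
simulate_confocal_stack <- function(n_inside = 60, n_invaded = 10,
                                    invasion_distances_um = c(10, 70),
                                    bead_radius_um = 50,
                                    nucleus_radius_mean_um = 4,
                                    nucleus_radius_sd_um = 0.3,
                                    spacing = c(dz = 4, dy = 1, dx = 1),
                                    blur_sigma_um = c(x = 0.8, y = 0.8, z = 2),
                                    noise_sd = 0.02,
                                    shot_noise_scale = NULL,
                                    min_separation_um = 9,
                                    margin_um = 8,
                                    seed = 1L,
                                    max_tries = 5000L) {
  check_positive_scalar(bead_radius_um, "bead_radius_um")
  if (n_inside < 0 || n_invaded < 0 || n_inside + n_invaded < 1) {
    stop_input("need at least one nucleus")
  }
  spacing <- spacing[c("dz", "dy", "dx")]
  with_seed(seed, {
    n_tot <- n_inside + n_invaded
    radii <- pmax(rnorm(n_tot, nucleus_radius_mean_um, nucleus_radius_sd_um), 1)
    if (n_invaded > 0) {
      if (length(invasion_distances_um) == 2L && n_invaded != 2L) {
        dists <- runif(n_invaded, invasion_distances_um[1], invasion_distances_um[2])
      } else if (length(invasion_distances_um) == n_invaded) {
        dists <- as.numeric(invasion_distances_um)
      } else {
        stop_input("`invasion_distances_um` must be a range or one value per invaded cell")
      }
      if (any(dists <= max(radii))) {
        stop_input(
          "invasion distances must exceed the largest nucleus radius (",
          sprintf("%.2f", max(radii)), " um), or resident and invaded cells are ambiguous"
        )
      }
    } else {
      dists <- numeric(0)
    }
    ext <- bead_radius_um + (if (n_invaded > 0) max(dists) else 0) +
      max(radii) + margin_um
    nv <- c(
      ceiling(2 * ext / spacing[["dy"]]) + 1,
      ceiling(2 * ext / spacing[["dx"]]) + 1,
      ceiling(2 * ext / spacing[["dz"]]) + 1
    )
    center <- c(
      x = (nv[[2]] - 1) / 2 * spacing[["dx"]],
      y = (nv[[1]] - 1) / 2 * spacing[["dy"]],
      z = (nv[[3]] - 1) / 2 * spacing[["dz"]]
    )
    pts <- matrix(NA_real_, n_tot, 3, dimnames = list(NULL, c("x", "y", "z")))
    place <- function(gen, i) {
      for (try in seq_len(max_tries)) {
        p <- gen()
        if (i == 1L) return(p)
        prev <- pts[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
        if (all(d2 >= min_separation_um^2)) return(p)
      }
      stop_input(
        "infeasible nucleus packing after ", max_tries, " tries: ",
        "reduce n_inside or min_separation_um"
      )
    }
    for (i in seq_len(n_inside)) {
      rmax <- bead_radius_um - radii[i]
      pts[i, ] <- place(function() {
        repeat {
          p <- runif(3, -rmax, rmax)
          if (sum(p^2) <= rmax^2) return(center + p[c(1, 2, 3)])
        }
      }, i)
    }
    for (j in seq_len(n_invaded)) {
      i <- n_inside + j
      pts[i, ] <- place(function() {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        center + (bead_radius_um + dists[j]) * u
      }, i)
    }
    # render anti-aliased spheres; soft edge one in-plane voxel wide
    img <- array(0, nv)
    edge <- min(spacing)
    for (i in seq_len(n_tot)) {
      r <- radii[i]
      iy <- max(1, floor((pts[i, "y"] - r - edge) / spacing[["dy"]]) + 1):
        min(nv[1], ceiling((pts[i, "y"] + r + edge) / spacing[["dy"]]) + 1)
      ix <- max(1, floor((pts[i, "x"] - r - edge) / spacing[["dx"]]) + 1):
        min(nv[2], ceiling((pts[i, "x"] + r + edge) / spacing[["dx"]]) + 1)
      iz <- max(1, floor((pts[i, "z"] - r - edge) / spacing[["dz"]]) + 1):
        min(nv[3], ceiling((pts[i, "z"] + r + edge) / spacing[["dz"]]) + 1)
      dy2 <- ((iy - 1) * spacing[["dy"]] - pts[i, "y"])^2
      dx2 <- ((ix - 1) * spacing[["dx"]] - pts[i, "x"])^2
      dz2 <- ((iz - 1) * spacing[["dz"]] - pts[i, "z"])^2
      dd <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
      val <- pmin(1, pmax(0, (r - dd) / edge + 0.5))
      img[iy, ix, iz] <- pmax(img[iy, ix, iz], val)
    }
    sig_vox <- c(
      blur_sigma_um[["y"]] / spacing[["dy"]],
      blur_sigma_um[["x"]] / spacing[["dx"]],
      blur_sigma_um[["z"]] / spacing[["dz"]]
    )
    if (any(sig_vox > 0)) img <- gaussian_smooth_3d(img, sig_vox)
    if (!is.null(shot_noise_scale)) {
      img <- array(rpois(length(img), pmax(img, 0) * shot_noise_scale) /
                     shot_noise_scale, nv)
    }
    if (noise_sd > 0) img <- img + array(rnorm(length(img), 0, noise_sd), nv)
    cdist <- sqrt((pts[, "x"] - center["x"])^2 +
                    (pts[, "y"] - center["y"])^2 +
                    (pts[, "z"] - center["z"])^2)
    list(
      stack = confocal_stack(img, spacing),
      truth = tibble::tibble(
        cell_id = seq_len(n_tot),
        x_um = pts[, "x"],
        y_um = pts[, "y"],
        z_um = pts[, "z"],
        radius_um = radii,
        invaded = rep(c(FALSE, TRUE), c(n_inside, n_invaded)),
        surface_distance_um = pmax(0, cdist - bead_radius_um)
      ),
      bead = structure(
        list(center = center, radius_um = bead_radius_um),
        class = "bead_model"
      )
    )
  })
}
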