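# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the brute-force Hough accumulator enumerates
# every (cx, cy, r) triple, the brute-force EDT scans every background
# voxel, the permutation p enumerates group splits, and the compound
# Poisson pmf comes from a Panjer-style convolution.

# Exhaustive circular Hough accumulator: counts edge pixels at rounded
# distance r from every candidate centre, normalised by perimeter.
brute_hough <- function(frame, radii, edge_threshold = 0.25) {
  H <- nrow(frame)
  W <- ncol(frame)
  gy <- (rbind(frame[-1, , drop = FALSE], frame[H, ]) -
           rbind(frame[1, ], frame[-H, , drop = FALSE])) / 2
  gx <- (cbind(frame[, -1, drop = FALSE], frame[, W]) -
           cbind(frame[, 1], frame[, -W, drop = FALSE])) / 2
  mag <- sqrt(gx^2 + gy^2)
  mag[c(1, H), ] <- 0
  mag[, c(1, W)] <- 0
  edge <- which(mag >= edge_threshold * max(mag))
  ey <- ((edge - 1) %% H) + 1
  ex <- ((edge - 1) %/% H) + 1
  cxs <- rep(seq_len(W), each = H)
  cys <- rep(seq_len(H), times = W)
  best <- c(score = -Inf, cx = NA, cy = NA, r = NA)
  for (r in radii) {
    score <- numeric(length(cxs))
    # distance from every candidate centre to every edge pixel
    for (k in seq_along(ex)) {
      d <- sqrt((cxs - ex[k])^2 + (cys - ey[k])^2)
      score <- score + (abs(d - r) < 0.5)
    }
    score <- score / (2 * pi * r)
    i <- which.max(score)
    if (score[i] > best["score"]) {
      best <- c(score = score[i], cx = cxs[i], cy = cys[i], r = r)
    }
  }
  best
}

# O(n^2) exact Euclidean distance transform for tiny 3D masks.
brute_edt3d <- function(mask, spacing_dim) {
  dims <- dim(mask)
  co <- arrayInd(seq_len(prod(dims)), dims)
  bg <- which(mask == 0)
  out <- numeric(prod(dims))
  for (i in which(mask != 0)) {
    out[i] <- sqrt(min(
      ((co[bg, 1] - co[i, 1]) * spacing_dim[1])^2 +
        ((co[bg, 2] - co[i, 2]) * spacing_dim[2])^2 +
        ((co[bg, 3] - co[i, 3]) * spacing_dim[3])^2
    ))
  }
  array(out, dims)
}

pooled_t <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n2))
}

# Exhaustive two-sided permutation p of the pooled t statistic.
exact_perm_p <- function(a, b) {
  x <- c(a, b)
  idx <- utils::combn(length(x), length(a))
  obs <- abs(pooled_t(a, b))
  ps <- apply(idx, 2, function(ii) abs(pooled_t(x[ii], x[-ii])))
  mean(ps >= obs - 1e-12)
}

# Monte-Carlo permutation p with n_resample draws.
mc_perm_p <- function(a, b, n_resample, seed) {
  x <- c(a, b)
  n1 <- length(a)
  obs <- abs(pooled_t(a, b))
  set.seed(seed)
  hits <- replicate(n_resample, {
    ii <- sample(length(x), n1)
    abs(pooled_t(x[ii], x[-ii])) >= obs - 1e-12
  })
  mean(hits)
}

# pmf of the compound Poisson(lambda_c) sum of geometric cluster sizes
# (P(size = s) = (1 - p) p^(s - 1)), by direct convolution over cluster
# counts — independent of the generator's sampling route.
compound_pois_geom_pmf <- function(lambda_c, p_agg, kmax) {
  # cluster-size pmf on 1..kmax
  gs <- (1 - p_agg) * p_agg^(0:(kmax - 1))
  pmf <- c(1, rep(0, kmax))  # point mass at 0 for zero clusters
  total <- dpois(0, lambda_c) * pmf
  conv <- pmf
  nmax <- max(20, ceiling(lambda_c + 10 * sqrt(lambda_c + 1)))
  for (n in seq_len(nmax)) {
    # convolve once more with the cluster-size pmf, truncated at kmax
    new <- numeric(kmax + 1)
    for (s in seq_len(kmax)) {
      contrib <- conv[seq_len(kmax + 1 - s)] * gs[s]
      new[(s + 1):(kmax + 1)] <- new[(s + 1):(kmax + 1)] + contrib
    }
    conv <- new
    total <- total + dpois(n, lambda_c) * conv
  }
  total  # P(K = 0..kmax), mass beyond kmax truncated
}

# Render anti-aliased spheres on an isotropic-or-not grid; independent of
# the package generator (no blur, no noise).
render_spheres <- function(centers, radii, dims, spacing) {
  arr <- array(0, dims)
  for (i in seq_len(nrow(centers))) {
    y2 <- ((seq_len(dims[1]) - 1) * spacing[["dy"]] - centers[i, 2])^2
    x2 <- ((seq_len(dims[2]) - 1) * spacing[["dx"]] - centers[i, 1])^2
    z2 <- ((seq_len(dims[3]) - 1) * spacing[["dz"]] - centers[i, 3])^2
    dd <- sqrt(outer(outer(y2, x2, "+"), z2, "+"))
    arr <- pmax(arr, pmin(1, pmax(0, radii[i] - dd + 0.5)))
  }
  arr
}
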