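# Circle detection in bright-field channel frames via the circular Hough
# transform with gradient-direction voting (the strategy behind MATLAB's
# imfindcircles): each edge pixel casts votes at +/- r along its gradient
# direction for every candidate radius, and accumulator peaks are refined
# by an algebraic (Kasa) circle fit on the supporting edge pixels.

shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

shift_zero <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) > 0L && length(cs) > 0L) {
    out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  }
  out
}

sobel_gradients <- function(m) {
  gx <- (shift_clamp(m, -1L, 1L) + 2 * shift_clamp(m, 0L, 1L) + shift_clamp(m, 1L, 1L)) -
    (shift_clamp(m, -1L, -1L) + 2 * shift_clamp(m, 0L, -1L) + shift_clamp(m, 1L, -1L))
  gy <- (shift_clamp(m, 1L, -1L) + 2 * shift_clamp(m, 1L, 0L) + shift_clamp(m, 1L, 1L)) -
    (shift_clamp(m, -1L, -1L) + 2 * shift_clamp(m, -1L, 0L) + shift_clamp(m, -1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  # border gradients use clamped samples; suppress them
  mag[c(1L, nrow(m)), ] <- 0
  mag[, c(1L, ncol(m))] <- 0
  list(gx = gx, gy = gy, mag = mag)
}

box3_sum <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out + shift_zero(m, dr, dc)
  out
}

empty_detections <- function() {
  tibble::tibble(
    center_x = numeric(), center_y = numeric(),
    radius = numeric(), score = numeric()
  )
}

# Algebraic least-squares circle fit (Kasa). Returns NULL when degenerate.
kasa_fit <- function(x, y) {
  if (length(x) < 5L) return(NULL)
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cx <- fit[1] / 2
  cy <- fit[2] / 2
  r2 <- fit[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = cx, cy = cy, r = sqrt(r2))
}

#' Detect circles in a grayscale frame
#'
#' Circular Hough transform over a configurable radius range. Edge pixels
#' (Sobel gradient magnitude above `edge_threshold` of the frame maximum)
#' vote at distance r along the positive and negative gradient direction
#' for each candidate radius r; votes are pooled in a 3x3 window and
#' normalised by circle perimeter, so a fully supported circle scores
#' around 1 or more and noise scores near 0. Accumulator peaks are
#' non-maximum-suppressed so that no two detections lie closer than
#' `min_separation`, then refined to sub-pixel centre and radius by a
#' least-squares circle fit on the supporting edge pixels.
#'
#' @param frame Numeric matrix, indexed `[y, x]`.
#' @param radius_range Length-2 numeric, min and max radius in pixels
#'   (both >= 3, min < max).
#' @param sensitivity Value in (0, 1]; peaks scoring at least
#'   `(1 - sensitivity)` of the strongest peak are kept (subject to
#'   `min_score`). Higher values admit weaker circles.
#' @param min_separation Minimum centre-to-centre distance between
#'   detections in pixels; defaults to the minimum search radius.
#' @param edge_threshold Fraction of the maximum gradient magnitude above
#'   which a pixel is treated as an edge.
#' @param min_score Absolute floor on the perimeter-normalised vote score.
#' @return A tibble with columns `center_x`, `center_y`, `radius`
#'   (pixels, sub-pixel precision) and `score`, sorted by descending
#'   score. Empty for blank or constant frames.
#' @export
detect_circles <- function(frame, radius_range, sensitivity = 0.9,
                           min_separation = NULL, edge_threshold = 0.25,
                           min_score = 0.25) {
  if (!is.matrix(frame) || nrow(frame) == 0L || ncol(frame) == 0L) {
    stop_input("`frame` must be a non-empty numeric matrix")
  }
  if (!is.numeric(radius_range) || length(radius_range) != 2L ||
      any(radius_range < 3) || radius_range[1] >= radius_range[2]) {
    stop_input("`radius_range` must be (low, high) with 3 <= low < high")
  }
  if (sensitivity <= 0 || sensitivity > 1) {
    stop_input("`sensitivity` must lie in (0, 1]")
  }
  H <- nrow(frame)
  W <- ncol(frame)
  if (is.null(min_separation)) min_separation <- radius_range[1]

  g <- sobel_gradients(frame)
  mmax <- max(g$mag)
  if (mmax <= 0) return(empty_detections())
  edge <- which(g$mag >= edge_threshold * mmax)
  if (length(edge) == 0L) return(empty_detections())
  ey <- ((edge - 1L) %% H) + 1L
  ex <- ((edge - 1L) %/% H) + 1L
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]

  radii <- seq(ceiling(radius_range[1]), floor(radius_range[2]), by = 1L)
  nr <- length(radii)
  score_best <- matrix(0, H, W)
  rad_best <- matrix(radii[1], H, W)
  for (ri in seq_len(nr)) {
    r <- radii[ri]
    votes <- numeric(H * W)
    for (sgn in c(-1, 1)) {
      cx <- round(ex + sgn * r * ux)
      cy <- round(ey + sgn * r * uy)
      ok <- cx >= 1 & cx <= W & cy >= 1 & cy <= H
      if (any(ok)) {
        lin <- cy[ok] + (cx[ok] - 1L) * H
        votes <- votes + tabulate(lin, nbins = H * W)
      }
    }
    sc <- box3_sum(matrix(votes, H, W)) / (2 * pi * r)
    upd <- sc > score_best
    score_best[upd] <- sc[upd]
    rad_best[upd] <- r
  }

  smax <- max(score_best)
  thr <- max(min_score, (1 - sensitivity) * smax)
  # 2D local maxima of the radius-collapsed score map
  is_peak <- score_best >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_peak <- is_peak & (score_best >= shift_zero(score_best, dr, dc))
  }
  peaks <- which(is_peak)
  if (length(peaks) == 0L) return(empty_detections())
  py <- ((peaks - 1L) %% H) + 1L
  px <- ((peaks - 1L) %/% H) + 1L
  ps <- score_best[peaks]
  pr <- rad_best[peaks]
  ord <- order(-ps, py, px)
  py <- py[ord]; px <- px[ord]; ps <- ps[ord]; pr <- pr[ord]

  keep <- logical(length(peaks))
  kx <- numeric(0)
  ky <- numeric(0)
  for (i in seq_along(peaks)) {
    if (length(kx) == 0L ||
        all((kx - px[i])^2 + (ky - py[i])^2 >= min_separation^2)) {
      keep[i] <- TRUE
      kx <- c(kx, px[i])
      ky <- c(ky, py[i])
    }
  }
  px <- px[keep]; py <- py[keep]; ps <- ps[keep]; pr <- pr[keep]

  out <- vector("list", length(px))
  for (i in seq_along(px)) {
    cx <- px[i]; cy <- py[i]; r <- pr[i]
    d <- sqrt((ex - cx)^2 + (ey - cy)^2)
    sup <- abs(d - r) <= 3
    fit <- kasa_fit(ex[sup], ey[sup])
    if (!is.null(fit) &&
        abs(fit$cx - cx) <= 2 && abs(fit$cy - cy) <= 2 &&
        fit$r >= radius_range[1] - 1 && fit$r <= radius_range[2] + 1) {
      cx <- fit$cx; cy <- fit$cy; r <- fit$r
    }
    out[[i]] <- tibble::tibble(
      center_x = cx, center_y = cy, radius = r, score = ps[i]
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$score))
}
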