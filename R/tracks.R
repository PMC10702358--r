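#' Detect circles in every frame of a sequence
#'
#' Runs [detect_circles()] on each frame and binds the detections into a
#' single tidy table with a `frame` column (1-based).
#'
#' @param fseq A [frame_sequence()].
#' @param radius_range,sensitivity,min_separation,edge_threshold,min_score
#'   Passed to [detect_circles()].
#' @return A tibble with columns `frame`, `center_x`, `center_y`,
#'   `radius`, `score`. The frame width/height and metadata are attached
#'   as attributes for downstream defaults.
#' @export
detect_droplets <- function(fseq, radius_range, sensitivity = 0.9,
                            min_separation = NULL, edge_threshold = 0.25,
                            min_score = 0.25) {
  stopifnot(inherits(fseq, "frame_sequence"))
  dets <- purrr::imap(fseq$frames, function(fr, i) {
    d <- detect_circles(fr, radius_range, sensitivity, min_separation,
                        edge_threshold, min_score)
    if (nrow(d) > 0L) d$frame <- as.integer(i)
    d
  })
  out <- dplyr::bind_rows(dets)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      frame = integer(), center_x = numeric(), center_y = numeric(),
      radius = numeric(), score = numeric()
    )
  }
  out <- dplyr::relocate(out, "frame")
  attr(out, "frame_width") <- fseq$width
  attr(out, "frame_height") <- fseq$height
  attr(out, "pixel_size") <- fseq$pixel_size
  attr(out, "fps") <- fseq$fps
  out
}

#' Link per-frame detections into droplet tracks
#'
#' Greedy nearest-neighbour association: candidate (track, detection)
#' pairs within `max_displacement` pixels and with at most `max_gap`
#' skipped frames are assigned in order of increasing distance; unmatched
#' detections start new tracks. Every detection ends up in exactly one
#' track. Greedy association is adequate here because droplets move
#' quasi-unidirectionally at roughly constant spacing; it is not a global
#' assignment and can mis-link crossing objects.
#'
#' @param detections Tibble from [detect_droplets()] (columns `frame`,
#'   `center_x`, `center_y`, at least).
#' @param max_displacement Maximum centre displacement (pixels) between
#'   linked detections.
#' @param max_gap Maximum number of skipped frames within a track
#'   (0 = consecutive frames only).
#' @return The input tibble with an integer `track` column, ordered by
#'   track then frame.
#' @export
link_tracks <- function(detections, max_displacement, max_gap = 0L) {
  check_positive_scalar(max_displacement, "max_displacement")
  atts <- attributes(detections)
  atts <- atts[intersect(c("frame_width", "frame_height", "pixel_size", "fps"),
                         names(atts))]
  if (nrow(detections) == 0L) {
    out <- dplyr::mutate(detections, track = integer())
    for (a in names(atts)) attr(out, a) <- atts[[a]]
    return(out)
  }
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- unique(detections$frame)
  track_of <- integer(nrow(detections))
  # active track state
  act_id <- integer(0)
  act_x <- numeric(0)
  act_y <- numeric(0)
  act_frame <- integer(0)
  next_id <- 1L
  for (f in frames) {
    idx <- which(detections$frame == f)
    dx <- detections$center_x[idx]
    dy <- detections$center_y[idx]
    live <- which(f - act_frame - 1L <= max_gap & act_frame < f)
    assigned_det <- logical(length(idx))
    used_track <- logical(length(live))
    if (length(live) > 0L) {
      dmat <- sqrt(outer(act_x[live], dx, "-")^2 + outer(act_y[live], dy, "-")^2)
      cand <- which(dmat <= max_displacement, arr.ind = TRUE)
      if (length(cand) > 0L) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        for (ci in seq_len(nrow(cand))) {
          ti <- cand[ci, 1L]
          di <- cand[ci, 2L]
          if (used_track[ti] || assigned_det[di]) next
          used_track[ti] <- TRUE
          assigned_det[di] <- TRUE
          tr <- live[ti]
          track_of[idx[di]] <- act_id[tr]
          act_x[tr] <- dx[di]
          act_y[tr] <- dy[di]
          act_frame[tr] <- f
        }
      }
    }
    for (di in which(!assigned_det)) {
      track_of[idx[di]] <- next_id
      act_id <- c(act_id, next_id)
      act_x <- c(act_x, dx[di])
      act_y <- c(act_y, dy[di])
      act_frame <- c(act_frame, f)
      next_id <- next_id + 1L
    }
    # retire tracks that can no longer be matched
    stale <- f - act_frame - 1L > max_gap
    if (any(stale)) {
      act_id <- act_id[!stale]
      act_x <- act_x[!stale]
      act_y <- act_y[!stale]
      act_frame <- act_frame[!stale]
    }
  }
  out <- dplyr::arrange(
    dplyr::mutate(detections, track = track_of),
    .data$track, .data$frame
  )
  for (a in names(atts)) attr(out, a) <- atts[[a]]
  out
}

#' Flag tracks that cross the centre line of the frame
#'
#' To prevent double counting, a droplet is counted once, and only if its
#' track crosses the (vertical) centre line of the frame: the sign of
#' `center_x - center_line_x` must change at least once along the track.
#' Samples lying exactly on the line are resolved by the next off-line
#' sample. A track crossing several times is still counted once.
#'
#' @param tracks Tibble from [link_tracks()].
#' @param center_line_x x-position of the counting line in pixels;
#'   defaults to half the frame width recorded by [detect_droplets()].
#' @return The input tibble with a logical `counted` column (constant
#'   within each track).
#' @export
count_center_crossings <- function(tracks, center_line_x = NULL) {
  if (is.null(center_line_x)) {
    w <- attr(tracks, "frame_width")
    if (is.null(w)) {
      stop_input("`center_line_x` is required when the table carries no frame width")
    }
    center_line_x <- w / 2
  }
  atts <- attributes(tracks)
  atts <- atts[intersect(c("frame_width", "frame_height", "pixel_size", "fps"),
                         names(atts))]
  out <- tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(counted = {
      s <- sign(.data$center_x - center_line_x)
      s <- s[s != 0]
      length(s) >= 2L && any(diff(s) != 0)
    }) |>
    dplyr::ungroup()
  for (a in names(atts)) attr(out, a) <- atts[[a]]
  out
}

#' Summarise the droplet size distribution
#'
#' Computes, over counted tracks only, the droplet count N, the mean
#' diameter `D_av` in micrometres, the population standard deviation, and
#' the dispersity (the standard deviation of the size distribution divided
#' by the mean diameter, reported as a percent) together with a diameter
#' histogram. Each track's diameter is the median of `2 * radius` over its
#' detections, converted with `pixel_size` — the median is robust to
#' partial detections at the frame edges.
#'
#' @param tracks Tibble from [count_center_crossings()].
#' @param pixel_size Pixel size in micrometres per pixel; defaults to the
#'   value recorded by [detect_droplets()].
#' @param n_bins Number of histogram bins.
#' @return A `size_summary` object; see [tidy.size_summary()],
#'   [glance.size_summary()] and [autoplot.size_summary()].
#' @export
summarize_sizes <- function(tracks, pixel_size = NULL, n_bins = 20L) {
  if (is.null(pixel_size)) pixel_size <- attr(tracks, "pixel_size")
  if (is.null(pixel_size)) {
    stop_input("`pixel_size` is required when the table carries no metadata")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  if (!"counted" %in% names(tracks)) {
    stop_input("run count_center_crossings() before summarize_sizes()")
  }
  per_track <- tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      diameter_um = stats::median(2 * .data$radius) * pixel_size,
      counted = .data$counted[1],
      .groups = "drop"
    )
  d <- per_track$diameter_um[per_track$counted]
  if (length(d) == 0L) {
    stop_input("no droplets counted: no track crosses the centre line")
  }
  d_av <- mean(d)
  sd_pop <- sqrt(mean((d - d_av)^2))  # population SD: distribution descriptor
  if (max(d) > min(d)) {
    breaks <- seq(min(d), max(d), length.out = n_bins + 1L)
    counts <- tabulate(
      findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE),
      nbins = n_bins
    )
  } else {
    breaks <- c(d[1] - 0.5, d[1] + 0.5)
    counts <- length(d)
  }
  structure(
    list(
      N = length(d),
      D_av_um = d_av,
      sd_um = sd_pop,
      dispersity = sd_pop / d_av,
      dispersity_percent = 100 * sd_pop / d_av,
      histogram = tibble::tibble(
        bin_left = breaks[-length(breaks)],
        bin_right = breaks[-1],
        count = counts
      ),
      tracks = per_track,
      pixel_size = pixel_size
    ),
    class = "size_summary"
  )
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(
    "<size_summary> N = %d counted droplets\n  D_av = %.2f um, sd = %.2f um, dispersity = %.2f%%\n",
    x$N, x$D_av_um, x$sd_um, x$dispersity_percent
  ))
  invisible(x)
}
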