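#' Read per-droplet cell counts from CSV
#'
#' Accepts either one row per droplet (columns `droplet_id`, `k_cells`)
#' or a pre-binned table (columns `k`, `count` with `k` in 0, 1, 2, "3+").
#' Pre-binned input is expanded to per-droplet counts; the open "3+" bin
#' is expanded as exactly 3 cells, which biases a subsequently estimated
#' lambda low — supply `lambda` explicitly downstream when the 3+ bin is
#' populated (a warning is raised).
#'
#' @param path CSV path (header row mandatory).
#' @return A tibble with `droplet_id` and `k_cells`.
#' @export
read_occupancy_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (all(c("droplet_id", "k_cells") %in% names(d))) {
    return(tibble::tibble(
      droplet_id = d$droplet_id,
      k_cells = as.integer(d$k_cells)
    ))
  }
  if (all(c("k", "count") %in% names(d))) {
    k <- gsub("\\s", "", as.character(d$k))
    open <- k == "3+"
    if (any(open) && any(d$count[open] > 0)) {
      warning("expanding the open '3+' bin as exactly 3 cells; ",
              "supply lambda explicitly for unbiased fits", call. = FALSE)
    }
    kv <- ifelse(open, 3L, suppressWarnings(as.integer(k)))
    if (any(is.na(kv))) stop_input("unrecognised k values in ", path)
    k_cells <- rep.int(kv, d$count)
    return(tibble::tibble(
      droplet_id = seq_along(k_cells),
      k_cells = as.integer(k_cells)
    ))
  }
  stop_input(
    "CSV must have columns droplet_id,k_cells or k,count: ", path
  )
}

#' Write per-track droplet sizes to CSV
#'
#' @param summary A `size_summary` from [summarize_sizes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(summary, path) {
  stopifnot(inherits(summary, "size_summary"))
  write.csv(summary$tracks, path, row.names = FALSE)
  invisible(path)
}

#' Write per-cell invasion results to CSV
#'
#' @param report An `invasion_report` from [classify_invasion()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(report, path) {
  stopifnot(inherits(report, "invasion_report"))
  write.csv(report$cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell regions CSV back into a regions tibble
#'
#' Allows re-analysis (bead estimation, invasion classification) without
#' re-segmenting the stack.
#'
#' @param path CSV written by [write_cells_csv()] or with at least
#'   `x_um`, `y_um`, `z_um`, `radius_um` columns.
#' @return A regions tibble.
#' @export
read_regions_csv <- function(path) {
  d <- tibble::as_tibble(read.csv(path))
  need <- c("x_um", "y_um", "z_um", "radius_um")
  if (!all(need %in% names(d))) {
    stop_input("regions CSV needs columns ", paste(need, collapse = ", "))
  }
  d
}

#' Write an analysis report as JSON
#'
#' Serialises the `glance()` row of a fitted object (plus any extra
#' fields) as a snake_case JSON object.
#'
#' @param x A `size_summary`, `occupancy_fit`, `invasion_report` or plain
#'   list.
#' @param path Output JSON path.
#' @param extra Named list of additional fields to include.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, extra = list()) {
  row <- if (is.list(x) && !is.object(x)) x else as.list(glance(x))
  jsonlite::write_json(c(row, extra), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a confocal stack to a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]`; one page per z-plane.
#'
#' @param stack A [confocal_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  planes <- lapply(seq_len(dim(stack$voxels)[3]), function(i) {
    pmin(pmax(stack$voxels[, , i], 0), 1)
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a confocal stack from a multi-page TIFF
#'
#' @param path TIFF path.
#' @param spacing Voxel spacing, named `c(dz=, dy=, dx=)` um.
#' @return A [confocal_stack()].
#' @export
read_stack_tiff <- function(path, spacing) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages) || is.array(pages)) pages <- list(pages)
  pages <- lapply(pages, as_gray_matrix)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  confocal_stack(arr, spacing)
}
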