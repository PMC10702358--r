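#' Construct a frame sequence
#'
#' Bundles a time-ordered set of 2D grayscale frames with the acquisition
#' metadata needed downstream: the pixel size in micrometres per pixel and
#' the frame rate. Frames are numeric matrices indexed `[y, x]` (row =
#' image row); pixel centres sit at integer coordinates starting at 1.
#'
#' @param frames List of numeric matrices, all with identical dimensions.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param fps Acquisition frame rate in frames per second (> 0).
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, pixel_size, fps) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_input("`frames` must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop_input("every frame must be a numeric matrix")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("all frames must share identical dimensions")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(fps, "fps")
  structure(
    list(
      frames = frames,
      pixel_size = pixel_size,
      fps = fps,
      height = nrow(frames[[1]]),
      width = ncol(frames[[1]])
    ),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(
    sprintf(
      "<frame_sequence> %d frames, %d x %d px, %.3g um/px, %.3g fps\n",
      length(x$frames), x$width, x$height, x$pixel_size, x$fps
    )
  )
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

as_gray_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L) {
    # average colour channels
    return(apply(img, c(1, 2), mean))
  }
  stop_input("unsupported image layout: expected matrix or H x W x C array")
}

#' Read a frame sequence from disk
#'
#' Reads either a multi-page TIFF or a directory of single-frame TIFF/PNG
#' images ordered lexicographically. Colour frames are converted to
#' grayscale by channel averaging.
#'
#' @param path Path to a multi-page TIFF file or to a directory of frames.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param fps Frame rate in frames per second.
#' @return A [frame_sequence()].
#' @export
read_frame_sequence <- function(path, pixel_size, fps) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop_input("no TIFF/PNG frames found in ", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE)) {
          stop_input("reading PNG frames requires the 'png' package")
        }
        as_gray_matrix(png::readPNG(f))
      } else {
        as_gray_matrix(tiff::readTIFF(f))
      }
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages) || is.array(pages)) pages <- list(pages)
    frames <- lapply(pages, as_gray_matrix)
  } else {
    stop_input("path not found: ", path)
  }
  frame_sequence(frames, pixel_size = pixel_size, fps = fps)
}

#' Write a frame sequence to a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` as required by the TIFF writer.
#'
#' @param x A [frame_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(x, path) {
  stopifnot(inherits(x, "frame_sequence"))
  frames <- lapply(x$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
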