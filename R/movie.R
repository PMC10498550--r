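#' Movie stacks
#'
#' A `movie_stack` is an ordered set of single-channel intensity frames with
#' the two physical calibrations every downstream measurement depends on:
#' pixel size (um/px) and frame rate (frames/s). Frames are stored as a
#' numeric `T x H x W` array; intensities are arbitrary (photon counts for
#' generated movies, camera units for real ones).
#'
#' @param frames numeric `T x H x W` array, or a list of equally sized
#'   matrices, of non-negative intensities.
#' @param pixel_size pixel size in um/px (> 0).
#' @param frame_rate acquisition rate in frames per second (> 0).
#' @param id identifier carried into all outputs.
#'
#' @return An object of class `movie_stack`.
#' @export
#' @examples
#' frames <- array(runif(4 * 8 * 8), dim = c(4, 8, 8))
#' m <- movie_stack(frames, pixel_size = 1, frame_rate = 50)
#' n_frames(m)
movie_stack <- function(frames, pixel_size, frame_rate, id = "fish") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      abort_invalid_input("All frames must have identical dimensions.")
    }
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort_invalid_input("`frames` must be a T x H x W array or list of matrices.")
  }
  if (dim(frames)[1] < 2L) {
    abort_invalid_input("A movie must contain at least 2 frames; no cardiac cycle is measurable from one frame.")
  }
  if (any(!is.finite(frames)) || any(frames < 0)) {
    abort_invalid_input("Frame intensities must be finite and non-negative.")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(frame_rate, "frame_rate")
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_rate = frame_rate,
         id = as.character(id)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie_stack '%s'> %d frames of %d x %d px | %.3g um/px | %.3g fps | %.3g s\n",
    x$id, d[1], d[2], d[3], x$pixel_size, x$frame_rate, d[1] / x$frame_rate))
  invisible(x)
}

#' @rdname movie_stack
#' @param movie a `movie_stack`.
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Total acquisition time of a movie, in seconds
#'
#' The record duration `n_frames / frame_rate`, the denominator of the
#' heart-rate calculation.
#'
#' @param movie a `movie_stack`.
#' @return seconds.
#' @export
acquisition_time <- function(movie) n_frames(movie) / movie$frame_rate

#' Read a multi-page TIFF time-lapse as a movie stack
#'
#' Pixel size and frame rate are mandatory calibration supplied by the caller:
#' TIFF metadata dialects are too inconsistent to trust silently, so embedded
#' resolution tags are ignored unless `use_embedded_tags = TRUE` (and even
#' then an explicit argument wins).
#'
#' @param path path to a multi-page TIFF.
#' @param pixel_size um/px; required unless an embedded x-resolution tag is
#'   present and `use_embedded_tags = TRUE`.
#' @param frame_rate frames per second; always required (TIFF has no standard
#'   frame-rate tag).
#' @param id identifier; defaults to the file name without extension.
#' @param use_embedded_tags if `TRUE`, fall back to the TIFF x-resolution tag
#'   for pixel size when `pixel_size` is missing.
#'
#' @return a [movie_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_rate = NULL,
                       id = NULL, use_embedded_tags = FALSE) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = use_embedded_tags),
    error = function(e) abort_io(sprintf("Could not read TIFF '%s': %s", path, conditionMessage(e)))
  )
  if (length(pages) == 0L) abort_io(sprintf("Empty TIFF: %s", path))
  if (length(pages) == 1L) {
    abort_invalid_input("Stack has a single frame; at least 2 are required.")
  }
  if (is.null(pixel_size) && use_embedded_tags) {
    xres <- attr(pages[[1]], "x.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0) pixel_size <- 1 / xres
  }
  if (is.null(pixel_size)) {
    abort_invalid_parameter("`pixel_size` (um/px) must be supplied; it is not read from metadata by default.")
  }
  if (is.null(frame_rate)) {
    abort_invalid_parameter("`frame_rate` (fps) must be supplied; TIFF carries no frame-rate tag.")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB
    p
  })
  movie_stack(pages, pixel_size = pixel_size, frame_rate = frame_rate,
              id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a movie stack to a multi-page TIFF
#'
#' Intensities are stored as 16-bit unsigned integers; values are clipped to
#' `[0, 65535]` and rounded. The calibrations are not embedded (see
#' [read_stack()]); keep them with the analysis configuration.
#'
#' @param movie a [movie_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  pages <- lapply(seq_len(n_frames(movie)), function(i) {
    p <- round(movie$frames[i, , ])
    p[p < 0] <- 0
    p[p > 65535] <- 65535
    p / 65535
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) abort_io(sprintf("Could not write TIFF '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Write a results table to CSV with a stable, documented column order
#'
#' Columns are written in the table's current order at full floating-point
#' precision. Units are part of the column names (`*_um2`, `*_nl`, `*_hz`),
#' so a written file is self-describing.
#'
#' @param table a non-empty data frame (per-fish cardiac parameters,
#'   per-frame geometry, a phenotype table, ...).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) abort_invalid_input("`table` must be a data frame.")
  if (nrow(table) == 0L) abort_invalid_input("Refusing to write an empty results table.")
  tryCatch(readr::write_csv(table, path),
           error = function(e) abort_io(sprintf("Could not write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}
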