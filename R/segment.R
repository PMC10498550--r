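#' Segment a single fluorescence frame
#'
#' Thresholds the frame (Otsu by default, which is parameter-free and
#' invariant to intensity scaling), fills interior holes (membrane-GFP
#' labelling produces annuli whose filled area is what chamber-area
#' measurements mean), and discards connected components smaller than
#' `min_area` pixels.
#'
#' @param frame numeric intensity matrix (H x W).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold intensity, required when
#'   `threshold_method = "fixed"`.
#' @param min_area minimum component area in pixels; smaller components are
#'   removed as noise.
#' @return logical mask matrix, same shape as `frame`.
#' @export
segment_frame <- function(frame, threshold_method = c("otsu", "fixed"),
                          fixed_value = NULL, min_area = 50) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort_invalid_input("`frame` must be a numeric matrix.")
  }
  rng <- range(frame)
  if (threshold_method == "otsu") {
    if (diff(rng) == 0) {
      abort_segmentation("Constant frame: Otsu threshold is undefined.")
    }
    scaled <- (frame - rng[1]) / diff(rng)
    thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    thr <- rng[1] + thr_scaled * diff(rng)
  } else {
    if (is.null(fixed_value)) {
      abort_invalid_parameter("`fixed_value` is required with threshold_method = \"fixed\".")
    }
    thr <- fixed_value
  }
  fg <- frame > thr
  if (!any(fg)) abort_segmentation("Empty foreground after thresholding.")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::fillHull(lab)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_area)
  mask <- matrix(as.integer(lab) %in% keep, nrow(frame), ncol(frame))
  if (!any(mask)) {
    abort_segmentation(sprintf("No component of at least %d px survives thresholding.", min_area))
  }
  mask
}

#' Select the ventricle component from a multi-chamber mask
#'
#' At 48 hpf in lateral view the ventricle dominates the myl7 signal, so
#' the default selector is the largest component; when the atrium wins (or
#' the view is unusual) a seed point inside the ventricle overrides it.
#'
#' @param mask logical mask, possibly with several connected components.
#' @param selector `"largest"` or `"nearest_to_point"`.
#' @param point pixel coordinates `c(row, col)`, required for
#'   `"nearest_to_point"`.
#' @return logical mask containing exactly one connected component.
#' @export
select_ventricle_component <- function(mask,
                                       selector = c("largest", "nearest_to_point"),
                                       point = NULL) {
  selector <- match.arg(selector)
  if (!any(mask)) abort_segmentation("Mask has no foreground component.")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  ids <- sort(unique(labm[labm > 0]))
  stats <- lapply(ids, function(id) {
    px <- which(labm == id, arr.ind = TRUE)
    list(id = id, size = nrow(px),
         centroid = colMeans(px), px = px)
  })
  chosen <- if (selector == "largest") {
    # tie on size broken by smaller centroid row, then column
    ord <- order(-vapply(stats, `[[`, 0, "size"),
                 vapply(stats, function(s) s$centroid[1], 0),
                 vapply(stats, function(s) s$centroid[2], 0))
    stats[[ord[1]]]
  } else {
    if (is.null(point) || length(point) != 2L) {
      abort_invalid_parameter("`point` = c(row, col) is required with selector = \"nearest_to_point\".")
    }
    d <- vapply(stats, function(s) {
      min(sqrt((s$px[, 1] - point[1])^2 + (s$px[, 2] - point[2])^2))
    }, 0)
    stats[[which.min(d)]]
  }
  labm == chosen$id
}

#' Segment every frame of a movie
#'
#' Runs [segment_frame()] and [select_ventricle_component()] on each frame,
#' then flags frames whose mask area deviates from the running median of
#' the area trace by more than `outlier_factor` (in either direction).
#' Flagged frames are reported, never silently kept; the area trace stage
#' interpolates across them.
#'
#' @param movie a [movie_stack()].
#' @param threshold_method,fixed_value,min_area passed to [segment_frame()].
#' @param selector,point passed to [select_ventricle_component()].
#' @param outlier_factor flag a frame when its area is more than this
#'   factor above (or below 1/factor of) the running median.
#' @param max_flagged_frac abort when more than this fraction of frames is
#'   flagged: the stack as a whole is then untrustworthy.
#' @return a `mask_stack`: list with `masks` (T x H x W logical array),
#'   `flagged` (integer frame indices), `areas_px` and the settings used.
#' @export
segment_stack <- function(movie, threshold_method = "otsu", fixed_value = NULL,
                          min_area = 50, selector = "largest", point = NULL,
                          outlier_factor = 3, max_flagged_frac = 0.2) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  d <- dim(movie$frames)
  masks <- array(FALSE, dim = d)
  areas <- rep(NA_real_, nt)
  failed <- integer(0)
  for (i in seq_len(nt)) {
    m <- tryCatch({
      m0 <- segment_frame(movie$frames[i, , ], threshold_method = threshold_method,
                          fixed_value = fixed_value, min_area = min_area)
      select_ventricle_component(m0, selector = selector, point = point)
    }, zfcardio_segmentation_error = function(e) NULL)
    if (is.null(m)) {
      failed <- c(failed, i)
    } else {
      masks[i, , ] <- m
      areas[i] <- sum(m)
    }
  }
  ok <- which(!is.na(areas))
  if (length(ok) == 0L) abort_segmentation("Segmentation failed in every frame.")
  # running median over ~1 cycle's worth of frames (odd window)
  k <- min(length(ok) - (length(ok) + 1) %% 2, 11L)
  refs <- if (k >= 3) stats::runmed(areas[ok], k) else rep(median(areas[ok]), length(ok))
  dev <- areas[ok] / refs
  outliers <- ok[dev > outlier_factor | dev < 1 / outlier_factor]
  flagged <- sort(unique(c(failed, outliers)))
  if (length(flagged) / nt > max_flagged_frac) {
    abort_segmentation(sprintf(
      "%d of %d frames flagged as segmentation failures (limit %.0f%%).",
      length(flagged), nt, 100 * max_flagged_frac))
  }
  structure(
    list(masks = masks, flagged = flagged, areas_px = areas,
         settings = list(threshold_method = threshold_method,
                         fixed_value = fixed_value, min_area = min_area,
                         selector = selector, point = point,
                         outlier_factor = outlier_factor)),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_stack> %d frames (%d x %d px), %d flagged, method=%s\n",
              d[1], d[2], d[3], length(x$flagged),
              x$settings$threshold_method))
  invisible(x)
}

#' Write a mask stack as a multi-page 8-bit TIFF (0/255)
#'
#' @param masks a `mask_stack` from [segment_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_stack"))
  pages <- lapply(seq_len(dim(masks$masks)[1]),
                  function(i) (masks$masks[i, , ]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
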