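#' Chamber area from a binary mask
#'
#' Foreground pixel count times the pixel area.
#'
#' @param mask logical mask.
#' @param pixel_size um/px.
#' @return area in um^2.
#' @export
mask_area <- function(mask, pixel_size) {
  check_positive_scalar(pixel_size, "pixel_size")
  n <- sum(mask)
  if (n == 0L) abort_invalid_input("Empty mask: area is undefined.")
  n * pixel_size^2
}

#' Long axis of a chamber mask
#'
#' The chamber length in the printed measurements is the apex-to-outflow
#' distance; automated, that is the extent of the mask along its first
#' principal axis. The direction is the leading eigenvector of the
#' second moments of the foreground pixel coordinates; the endpoints are
#' the two extreme foreground pixels by projection onto that direction
#' (projection ties broken by pixel scan order). The two ends are not
#' distinguished: length is symmetric.
#'
#' @param mask logical mask with at least 3 foreground pixels.
#' @return list with `direction` (unit vector, `c(drow, dcol)`),
#'   `endpoints` (2 x 2 matrix of pixel `(row, col)` coordinates) and
#'   `midpoint`.
#' @export
long_axis <- function(mask) {
  px <- which(mask, arr.ind = TRUE)  # column-major scan order
  if (nrow(px) < 3L) {
    abort_geometry("Mask has fewer than 3 foreground pixels; no axis is defined.")
  }
  ctr <- colMeans(px)
  cen <- sweep(px, 2, ctr)
  cv <- crossprod(cen) / nrow(px)
  eg <- eigen(cv, symmetric = TRUE)
  dir <- eg$vectors[, 1]
  proj <- cen %*% dir
  i_min <- which.min(proj)  # which.min/max return the first, i.e. scan order
  i_max <- which.max(proj)
  endpoints <- rbind(px[i_min, ], px[i_max, ])
  rownames(endpoints) <- NULL
  list(direction = dir, endpoints = endpoints,
       midpoint = colMeans(endpoints))
}

#' Chamber length along the long axis
#'
#' Euclidean distance between the long-axis endpoints, scaled to um.
#'
#' @param mask logical mask.
#' @param pixel_size um/px.
#' @param axis optional precomputed [long_axis()].
#' @return length in um.
#' @export
chamber_length <- function(mask, pixel_size, axis = NULL) {
  check_positive_scalar(pixel_size, "pixel_size")
  axis <- axis %||% long_axis(mask)
  sqrt(sum((axis$endpoints[1, ] - axis$endpoints[2, ])^2)) * pixel_size
}

#' Chamber diameter at the middle of the length measurement
#'
#' The chord of the mask along the line perpendicular to the long axis
#' through the axis midpoint: the distance between the first and the last
#' foreground sample on that line. The line is sampled at 0.25-pixel steps
#' to reduce aliasing on rasterised boundaries.
#'
#' @param mask logical mask.
#' @param pixel_size um/px.
#' @param axis optional precomputed [long_axis()].
#' @param step sampling step along the chord, in pixels.
#' @return diameter in um.
#' @export
chamber_diameter <- function(mask, pixel_size, axis = NULL, step = 0.25) {
  check_positive_scalar(pixel_size, "pixel_size")
  axis <- axis %||% long_axis(mask)
  perp <- c(-axis$direction[2], axis$direction[1])
  mid <- axis$midpoint
  half <- ceiling(sqrt(nrow(mask)^2 + ncol(mask)^2))
  s <- seq(-half, half, by = step)
  rr <- round(mid[1] + s * perp[1])
  cc <- round(mid[2] + s * perp[2])
  inb <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  fg <- rep(FALSE, length(s))
  fg[inb] <- mask[cbind(rr[inb], cc[inb])]
  if (!any(fg)) {
    abort_geometry("Perpendicular chord at the axis midpoint misses the mask foreground.")
  }
  hit <- range(s[fg])
  (hit[2] - hit[1]) * pixel_size
}

#' Per-frame chamber geometry
#'
#' Bundles the three measured quantities (area, length, diameter) for one
#' frame's mask. A diameter exceeding the length (a nearly spherical or
#' mis-oriented chamber) is reported with a warning but kept: it is a
#' property of the data, not an error.
#'
#' @param mask logical mask.
#' @param pixel_size um/px.
#' @param frame_index frame number recorded in the output.
#' @return one-row tibble: `frame`, `area_um2`, `length_um`,
#'   `diameter_um`, axis endpoints in um
#'   (`apex_x_um`, `apex_y_um`, `base_x_um`, `base_y_um`), `flagged`.
#' @export
frame_geometry <- function(mask, pixel_size, frame_index = 1L) {
  area <- mask_area(mask, pixel_size)
  axis <- long_axis(mask)
  len <- chamber_length(mask, pixel_size, axis = axis)
  dia <- chamber_diameter(mask, pixel_size, axis = axis)
  if (dia > len) {
    warn(sprintf("Frame %d: diameter (%.1f um) exceeds length (%.1f um); chamber nearly spherical or axis mis-oriented.",
                 frame_index, dia, len))
  }
  ep <- axis$endpoints
  dimnames(ep) <- NULL
  tibble(
    frame = as.integer(frame_index),
    area_um2 = area, length_um = len, diameter_um = dia,
    apex_x_um = ep[1, 2] * pixel_size, apex_y_um = ep[1, 1] * pixel_size,
    base_x_um = ep[2, 2] * pixel_size, base_y_um = ep[2, 1] * pixel_size,
    flagged = FALSE
  )
}

#' Geometry of every frame in a segmented stack
#'
#' Applies [frame_geometry()] to each frame of a `mask_stack`. Frames that
#' were flagged by [segment_stack()] (or whose geometry fails) get `NA`
#' measurements and `flagged = TRUE`; the area-trace stage interpolates
#' across them.
#'
#' @param masks a `mask_stack` from [segment_stack()].
#' @param pixel_size um/px.
#' @return tibble with one row per frame (schema of [frame_geometry()]).
#' @export
stack_geometry <- function(masks, pixel_size) {
  stopifnot(inherits(masks, "mask_stack"))
  nt <- dim(masks$masks)[1]
  na_row <- function(i) tibble(
    frame = as.integer(i), area_um2 = NA_real_, length_um = NA_real_,
    diameter_um = NA_real_, apex_x_um = NA_real_, apex_y_um = NA_real_,
    base_x_um = NA_real_, base_y_um = NA_real_, flagged = TRUE)
  rows <- lapply(seq_len(nt), function(i) {
    if (i %in% masks$flagged) return(na_row(i))
    tryCatch(
      suppressWarnings(frame_geometry(masks$masks[i, , ], pixel_size, i)),
      zfcardio_geometry_error = function(e) na_row(i),
      zfcardio_invalid_input = function(e) na_row(i))
  })
  bind_rows(rows)
}
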