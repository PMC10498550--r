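#' Ventricle area trace over time
#'
#' Ordered per-frame chamber areas from a geometry table, with flagged
#' frames linearly interpolated from their nearest measured neighbours
#' (constant extrapolation at the record ends). The number of interpolated
#' frames is attached as an attribute and reported.
#'
#' @param geometries tibble from [stack_geometry()] (needs `frame`,
#'   `area_um2`, `flagged`).
#' @return numeric vector of areas (um^2), one per frame, with attribute
#'   `n_interpolated`.
#' @export
area_trace <- function(geometries) {
  stopifnot(is.data.frame(geometries))
  g <- dplyr::arrange(geometries, .data$frame)
  if (nrow(g) < 2L) abort_invalid_input("At least 2 frames are required.")
  a <- g$area_um2
  bad <- which(is.na(a) | g$flagged)
  if (length(bad) == nrow(g)) {
    abort_cycles("Every frame is flagged; no area trace can be formed.")
  }
  if (length(bad) > 0) {
    ok <- setdiff(seq_along(a), bad)
    a[bad] <- approx(ok, a[ok], xout = bad, rule = 2)$y
  }
  structure(a, n_interpolated = length(bad))
}

#' Construct a cycle set
#'
#' Container for detected end-diastole (ED, area maxima) and end-systole
#' (ES, area minima) frames and their pairing into contraction cycles.
#' Normally produced by [detect_extrema()]; the constructor is exported so
#' that cycle sets can be built from known frame indices.
#'
#' @param ed_frames,es_frames integer frame indices (1-based).
#' @param acquisition_time record duration in seconds.
#' @param pairs optional tibble with columns `ed`, `es`; derived by pairing
#'   each ED with the next ES when omitted.
#' @param period_frames estimated period in frames (optional).
#' @param trace the area trace the set was detected on (optional).
#' @param settings detection settings record (optional).
#' @return an object of class `cycle_set`.
#' @export
cycle_set <- function(ed_frames, es_frames, acquisition_time,
                      pairs = NULL, period_frames = NA_real_,
                      trace = NULL, settings = list()) {
  check_positive_scalar(acquisition_time, "acquisition_time")
  ed_frames <- sort(as.integer(ed_frames))
  es_frames <- sort(as.integer(es_frames))
  if (is.null(pairs)) {
    pr <- lapply(ed_frames, function(e) {
      nxt <- es_frames[es_frames > e]
      nxt_ed <- ed_frames[ed_frames > e]
      if (length(nxt) == 0) return(NULL)
      if (length(nxt_ed) > 0 && nxt_ed[1] < nxt[1]) return(NULL)
      tibble(ed = e, es = nxt[1])
    })
    pairs <- bind_rows(pr)
  }
  structure(
    list(ed_frames = ed_frames, es_frames = es_frames, pairs = pairs,
         acquisition_time = acquisition_time, period_frames = period_frames,
         trace = trace, settings = settings),
    class = "cycle_set"
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d ED, %d ES, %d pairs | %.3g s record | period ~%.3g frames\n",
              length(x$ed_frames), length(x$es_frames), nrow(x$pairs),
              x$acquisition_time, x$period_frames))
  invisible(x)
}

# Local extrema of a trace, endpoints included: the record is not
# phase-locked to the heartbeat, so a boundary frame that dominates its
# one-sided neighbourhood is a genuine ED/ES and excluding it would bias
# the ED-to-ED cycle count low in short records. Ties keep the earlier
# frame. Returns candidate indices.
local_extrema <- function(x, maxima = TRUE) {
  if (!maxima) x <- -x
  n <- length(x)
  idx <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1L  # plateau
    left_ok <- i == 1L || x[i - 1] < x[i]
    right_ok <- j == n || x[j + 1] < x[i]
    if (left_ok && right_ok) idx <- c(idx, i)  # earlier frame of a plateau
    i <- j + 1L
  }
  idx
}

# Prominence of extrema: height above the higher of the two flanking
# valleys (segments to the neighbouring candidate of the same type, or to
# the record boundary).
extremum_prominence <- function(x, idx, maxima = TRUE) {
  if (!maxima) x <- -x
  n <- length(x)
  vapply(seq_along(idx), function(k) {
    i <- idx[k]
    lo <- if (k == 1L) 1L else idx[k - 1L]
    hi <- if (k == length(idx)) n else idx[k + 1L]
    left_base <- if (i > lo) min(x[lo:(i - 1L)]) else x[i]
    right_base <- if (i < hi) min(x[(i + 1L):hi]) else x[i]
    bases <- c(left_base, right_base)[c(i > lo, i < hi)]
    if (length(bases) == 0) return(0)
    x[i] - max(bases)
  }, 0)
}

# Enforce a minimum separation between same-type extrema, dropping the
# weaker of any close pair (tie: keep the earlier).
enforce_separation <- function(idx, strength, min_sep) {
  while (length(idx) > 1L) {
    gaps <- diff(idx)
    close <- which(gaps < min_sep)
    if (length(close) == 0L) break
    k <- close[1L]
    drop <- if (strength[k + 1L] > strength[k]) k else k + 1L
    idx <- idx[-drop]
    strength <- strength[-drop]
  }
  idx
}

#' Detect end-diastole and end-systole frames from an area trace
#'
#' End-diastole frames are local maxima of the ventricle-area trace (the
#' filled chamber is largest at maximal filling) and end-systole frames
#' local minima. The dominant period is first estimated from the FFT peak
#' of the mean-subtracted trace; extrema are then required to be separated
#' by at least `min_separation` periods and to have prominence at least
#' `min_prominence` of the trace range. Alternation is enforced by
#' dropping the weaker of two same-type consecutive extrema, and each ED
#' is paired with the next ES.
#'
#' @param trace numeric area trace (from [area_trace()]).
#' @param frame_rate frames per second.
#' @param min_separation minimum separation between same-type extrema, as
#'   a fraction of the estimated period.
#' @param min_prominence minimum extremum prominence, as a fraction of the
#'   trace range.
#' @param peak_snr minimum ratio of the dominant FFT peak power to the
#'   median off-peak power; below it the trace is declared aperiodic.
#' @return a [cycle_set()].
#' @export
detect_extrema <- function(trace, frame_rate, min_separation = 0.6,
                           min_prominence = 0.1, peak_snr = 5) {
  check_positive_scalar(frame_rate, "frame_rate")
  n <- length(trace)
  if (n < 4L) abort_cycles("Trace too short for cycle detection.")
  z <- trace - mean(trace)
  pw <- Mod(fft(z))^2
  half <- pw[2:(floor(n / 2) + 1)]          # positive frequencies
  k <- which.max(half)                      # cycles per record
  if (half[k] < peak_snr * median(half) || max(half) == 0) {
    abort_cycles("No spectral peak above the noise floor; trace is not periodic.")
  }
  if (k < 2L) {
    abort_cycles("Record spans fewer than 2 periods of the dominant frequency; cycles cannot be delimited.")
  }
  period_frames <- n / k
  rng <- diff(range(trace))
  if (rng == 0) abort_cycles("Constant trace: no cycles.")
  min_sep <- min_separation * period_frames
  min_prom <- min_prominence * rng

  pick <- function(maxima) {
    idx <- local_extrema(trace, maxima)
    prom <- extremum_prominence(trace, idx, maxima)
    keep <- prom >= min_prom
    idx <- idx[keep]; prom <- prom[keep]
    enforce_separation(idx, prom, min_sep)
  }
  ed <- pick(TRUE)
  es <- pick(FALSE)
  interior <- function(i) i > 1L & i < n
  if (!any(interior(ed)) || !any(interior(es))) {
    abort_cycles("No interior extrema found; trace is not periodic within the record.")
  }

  # enforce strict alternation on the merged sequence
  ev <- tibble(frame = c(ed, es),
               type = rep(c("ed", "es"), c(length(ed), length(es))),
               height = trace[c(ed, es)])
  ev <- dplyr::arrange(ev, .data$frame)
  repeat {
    same <- which(ev$type[-1] == ev$type[-nrow(ev)])
    if (length(same) == 0L) break
    k2 <- same[1L]
    # of two consecutive same-type extrema keep the stronger (higher ED /
    # lower ES); tie keeps the earlier
    a <- ev$height[k2]; b <- ev$height[k2 + 1L]
    better_second <- if (ev$type[k2] == "ed") b > a else b < a
    ev <- ev[-(if (better_second) k2 else k2 + 1L), ]
  }
  ed <- ev$frame[ev$type == "ed"]
  es <- ev$frame[ev$type == "es"]
  if (length(ed) == 0L || length(es) == 0L) {
    abort_cycles("Fewer than one complete ED/ES pair detected.")
  }
  cs <- cycle_set(ed, es, acquisition_time = n / frame_rate,
                  period_frames = period_frames, trace = as.numeric(trace),
                  settings = list(min_separation = min_separation,
                                  min_prominence = min_prominence,
                                  peak_snr = peak_snr,
                                  frame_rate = frame_rate))
  if (nrow(cs$pairs) < 1L) {
    abort_cycles("Fewer than one complete ED/ES pair detected.")
  }
  bad <- cs$trace[cs$pairs$ed] <= cs$trace[cs$pairs$es]
  if (!is.null(cs$trace) && any(bad)) {
    cs$pairs <- cs$pairs[!bad, , drop = FALSE]
  }
  cs
}

#' Heart rate from a cycle set
#'
#' Number of complete cycles divided by the acquisition time, in beats per
#' second. A complete cycle is one ED-to-ED interval fully contained in
#' the record, so `n_cycles = n_ED - 1`.
#'
#' @param cycles a [cycle_set()].
#' @return heart rate in Hz.
#' @export
heart_rate <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  n_cycles <- length(cycles$ed_frames) - 1L
  if (n_cycles < 1L) {
    abort_cycles("At least one complete ED-to-ED cycle is required for heart rate.")
  }
  n_cycles / cycles$acquisition_time
}

#' @describeIn cycle_set `tidy()` returns one row per detected extremum
#'   (`frame`, `type`, `area_um2` when a trace is attached).
#' @param x a `cycle_set`.
#' @param ... unused.
#' @export
tidy.cycle_set <- function(x, ...) {
  out <- tibble(
    frame = c(x$ed_frames, x$es_frames),
    type = rep(c("ED", "ES"), c(length(x$ed_frames), length(x$es_frames))))
  if (!is.null(x$trace)) out$area_um2 <- x$trace[out$frame]
  dplyr::arrange(out, .data$frame)
}

#' @describeIn cycle_set `glance()` returns a one-row summary
#'   (counts, period, heart rate).
#' @export
glance.cycle_set <- function(x, ...) {
  hr <- if (length(x$ed_frames) >= 2L) heart_rate(x) else NA_real_
  tibble(
    n_ed = length(x$ed_frames), n_es = length(x$es_frames),
    n_pairs = nrow(x$pairs), period_frames = x$period_frames,
    acquisition_time_s = x$acquisition_time, hr_hz = hr)
}

#' Plot an area trace with detected extrema
#'
#' @param object a `cycle_set` with an attached trace.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cycle_set <- function(object, ...) {
  if (is.null(object$trace)) {
    abort_invalid_input("This cycle_set carries no area trace to plot.")
  }
  df <- tibble(frame = seq_along(object$trace), area_um2 = object$trace)
  ex <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$area_um2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = ex,
                        ggplot2::aes(colour = .data$type), size = 2) +
    ggplot2::scale_colour_manual(values = c(ED = "#2166ac", ES = "#b2182b")) +
    ggplot2::labs(x = "frame", y = expression(ventricle~area~(mu*m^2)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
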