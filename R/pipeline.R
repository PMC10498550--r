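with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)),
          class = c(class(e)[1], "zfcardio_pipeline_error"), parent = e)
  })
}

#' Quantify cardiac function of one fish from a movie
#'
#' The full measurement chain on one time-lapse: per-frame ventricle
#' segmentation, per-frame geometry (area, length, diameter), end-diastole
#' / end-systole detection on the area trace, per-cycle chamber equations,
#' and the per-fish average over all captured cycles. Errors carry a stage
#' label so failed fish are auditable.
#'
#' @param movie a [movie_stack()].
#' @param min_cycles minimum ED/ES pairs required to report the fish
#'   (default 3).
#' @param segmentation list of options for [segment_stack()].
#' @param detection list of options for [detect_extrema()].
#' @param keep_masks retain the mask stack in the result (memory-heavy).
#' @return a `fish_result` list: `params` (one-row per-fish tibble),
#'   `cycle_measurements`, `cycles` (the [cycle_set()]), `geometry`,
#'   and optionally `masks`.
#' @export
#' @examples
#' sim <- generate_beating_movie(generator_config(seed = 3))
#' res <- run_fish(sim$movie)
#' res$params$EF_pct
run_fish <- function(movie, min_cycles = 3L, segmentation = list(),
                     detection = list(), keep_masks = FALSE) {
  stopifnot(inherits(movie, "movie_stack"))
  masks <- with_stage("segmentation",
                      do.call(segment_stack, c(list(movie), segmentation)))
  geom <- with_stage("geometry", stack_geometry(masks, movie$pixel_size))
  trace <- with_stage("area-trace", area_trace(geom))
  cycles <- with_stage("cycle-detection",
                       do.call(detect_extrema,
                               c(list(trace, movie$frame_rate), detection)))
  meas <- with_stage("cardiac-parameters", {
    rows <- lapply(seq_len(nrow(cycles$pairs)), function(i) {
      edr <- geom[cycles$pairs$ed[i], ]
      esr <- geom[cycles$pairs$es[i], ]
      if (any(is.na(c(edr$length_um, esr$length_um)))) return(NULL)
      tryCatch(cycle_measurement(edr, esr),
               zfcardio_invalid_pair = function(e) NULL)
    })
    bind_rows(rows)
  })
  hr <- with_stage("heart-rate", heart_rate(cycles))
  params <- with_stage("per-fish-summary",
                       per_fish_summary(meas, hr, min_cycles = min_cycles,
                                        id = movie$id))
  inform(sprintf(
    "zfcardio: fish '%s': %d frames, %d flagged, %d ED / %d ES, %d cycles used, HR %.2f Hz",
    movie$id, n_frames(movie), length(masks$flagged),
    length(cycles$ed_frames), length(cycles$es_frames), nrow(meas), hr))
  out <- list(params = params, cycle_measurements = meas, cycles = cycles,
              geometry = geom)
  if (keep_masks) out$masks <- masks
  structure(out, class = "fish_result")
}

#' @export
print.fish_result <- function(x, ...) {
  cat("<fish_result>\n")
  print(x$params)
  invisible(x)
}

#' @describeIn run_fish `tidy()` of a `fish_result` returns the per-cycle
#'   measurements.
#' @param x a `fish_result`.
#' @param ... unused.
#' @export
tidy.fish_result <- function(x, ...) x$cycle_measurements

#' @describeIn run_fish `glance()` of a `fish_result` returns the one-row
#'   per-fish parameter summary.
#' @export
glance.fish_result <- function(x, ...) x$params

#' @describeIn run_fish `autoplot()` of a `fish_result` shows the area
#'   trace with detected extrema.
#' @param object a `fish_result`.
#' @export
autoplot.fish_result <- function(object, ...) autoplot(object$cycles, ...)

#' Cohort-level comparison of per-fish cardiac parameters
#'
#' Per-group mean and SEM for each requested parameter, a one-way ANOVA
#' across groups per parameter, and (optionally) an NV/SV classification
#' of every fish against a control group's EDV distribution followed by
#' Fisher's exact test on the resulting phenotype proportions. P-values
#' are per comparison; no multiplicity adjustment is applied.
#'
#' @param fish_params tibble of per-fish parameters
#'   ([per_fish_summary()] rows, one per fish).
#' @param groups character/factor vector assigning each row to a group,
#'   or the name of a column of `fish_params`.
#' @param parameters parameter columns to compare.
#' @param classify_against optional control group name; when given, every
#'   fish is classified NV/SV against that group's EDV distribution and a
#'   2x2 Fisher test (control vs each other group) is run on the counts.
#' @param quantile SV classification quantile (see
#'   [classify_ventricle()]).
#' @param welch use Welch's ANOVA.
#' @return a `cohort_result` list: `group_summary`, `anova`,
#'   and optionally `classification` and `fisher`.
#' @export
run_cohort <- function(fish_params, groups,
                       parameters = c("EF_pct", "FS", "FAC_pct", "SV_nl",
                                      "CO_nl_per_s", "HR_hz"),
                       classify_against = NULL, quantile = 0.05,
                       welch = FALSE) {
  stopifnot(is.data.frame(fish_params))
  if (is.character(groups) && length(groups) == 1L &&
      groups %in% names(fish_params)) {
    groups <- fish_params[[groups]]
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(fish_params)) {
    abort_invalid_input("`groups` must assign one group per fish.")
  }
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("At least 2 groups with at least 2 fish each are required.",
          class = "zfcardio_invalid_cohort")
  }
  parameters <- intersect(parameters, names(fish_params))
  if (length(parameters) == 0L) {
    abort_invalid_input("None of the requested parameters are present in `fish_params`.")
  }
  df <- dplyr::mutate(as_tibble(fish_params), .group = groups)
  group_summary <- df |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$.group, .data$parameter) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::rename(group = ".group")
  anova_tab <- bind_rows(lapply(parameters, function(p) {
    res <- tryCatch(
      one_way_anova(split(df[[p]], df$.group), welch = welch),
      zfcardio_degenerate_error = function(e)
        tibble(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
               p_value = NA_real_, method = "degenerate (no variance)"))
    dplyr::mutate(res, parameter = p, .before = 1)
  }))
  out <- list(group_summary = group_summary, anova = anova_tab)
  if (!is.null(classify_against)) {
    if (!classify_against %in% names(tab)) {
      abort_invalid_input(sprintf("Control group '%s' not found.", classify_against))
    }
    ctrl_edv <- df$EDV_um3[df$.group == classify_against]
    cls <- classify_ventricle(df$EDV_um3, ctrl_edv, quantile = quantile)
    cls$group <- df$.group
    counts <- cls |>
      dplyr::count(.data$group, .data$label) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n",
                         values_fill = 0L)
    for (col in c("NV", "SV")) if (!col %in% names(counts)) counts[[col]] <- 0L
    others <- setdiff(counts$group, classify_against)
    fisher <- bind_rows(lapply(others, function(gother) {
      m <- as.matrix(counts[match(c(classify_against, gother), counts$group),
                            c("NV", "SV")])
      res <- tryCatch(fisher_exact_2x2(m),
                      zfcardio_degenerate_error = function(e)
                        tibble(p_value = NA_real_, odds_ratio = NA_real_,
                               method = "degenerate (zero margin)"))
      dplyr::mutate(res, comparison = paste(classify_against, "vs", gother),
                    .before = 1)
    }))
    out$classification <- cls
    out$fisher <- fisher
  }
  structure(out, class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n$group_summary\n")
  print(x$group_summary)
  cat("\n$anova\n")
  print(x$anova)
  if (!is.null(x$fisher)) {
    cat("\n$fisher\n")
    print(x$fisher)
  }
  invisible(x)
}

#' @describeIn run_cohort `tidy()` of a `cohort_result` returns the
#'   per-group summary table.
#' @param x a `cohort_result`.
#' @param ... unused.
#' @export
tidy.cohort_result <- function(x, ...) x$group_summary

#' @describeIn run_cohort `glance()` of a `cohort_result` returns the
#'   per-parameter ANOVA table.
#' @export
glance.cohort_result <- function(x, ...) x$anova

#' @describeIn run_cohort `autoplot()` of a `cohort_result` draws
#'   per-group means with SEM error bars, one facet per parameter.
#' @param object a `cohort_result`.
#' @export
autoplot.cohort_result <- function(object, ...) {
  ggplot2::ggplot(object$group_summary,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean +/- SEM") +
    ggplot2::theme_minimal()
}

#' Parameter-recovery benchmark on synthetic movies
#'
#' Generates movies over a grid of noise levels and seeds, runs the full
#' pipeline on each, and tabulates the recovery of EF, SV, HR and CO
#' against the generator's ground truth (bias and RMSE per noise level).
#' Noise level 0 is the noiseless limit (no shot noise, no read noise);
#' level 1 is the default camera model; higher levels divide the signal
#' and multiply the read noise by the level.
#'
#' @param noise_levels numeric vector of noise levels (see above).
#' @param seeds integer seeds; each (level, seed) cell is one movie.
#' @param config base [generator_config()] to perturb.
#' @return a `zf_benchmark` list: `runs` (per-movie true vs estimated
#'   values) and `cells` (bias and RMSE per noise level and parameter).
#' @export
benchmark_recovery <- function(noise_levels = c(0, 1, 2),
                               seeds = 1:5,
                               config = generator_config()) {
  grid <- expand.grid(noise = noise_levels, seed = as.integer(seeds))
  runs <- bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    nl <- grid$noise[i]; sd_ <- grid$seed[i]
    args <- unclass(config)
    args$seed <- sd_
    if (nl == 0) {
      args$shot_noise <- FALSE
      args$read_noise_sd <- 0
    } else {
      args$signal_level <- config$signal_level / nl
      args$read_noise_sd <- config$read_noise_sd * nl
    }
    sim <- generate_beating_movie(do.call(generator_config, args))
    est <- suppressMessages(run_fish(sim$movie))
    tr <- sim$truth$params
    tibble(
      noise = nl, seed = sd_,
      EF_true = tr$EF_pct, EF_est = est$params$EF_pct,
      SV_true = tr$SV_um3, SV_est = est$params$SV_um3,
      HR_true = tr$HR_hz, HR_est = est$params$HR_hz,
      CO_true = tr$CO_um3_per_s, CO_est = est$params$CO_um3_per_s)
  }))
  long <- runs |>
    tidyr::pivot_longer(-c("noise", "seed"),
                        names_to = c("parameter", "kind"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  cells <- long |>
    dplyr::group_by(.data$noise, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias = mean(.data$est - .data$true),
      rmse = sqrt(mean((.data$est - .data$true)^2)),
      rel_rmse = sqrt(mean(((.data$est - .data$true) / .data$true)^2)),
      .groups = "drop")
  structure(list(runs = runs, cells = cells), class = "zf_benchmark")
}

#' @export
print.zf_benchmark <- function(x, ...) {
  cat("<zf_benchmark>\n")
  print(x$cells)
  invisible(x)
}

#' @describeIn benchmark_recovery `autoplot()` shows RMSE against noise
#'   level per parameter.
#' @param object a `zf_benchmark`.
#' @param ... unused.
#' @export
autoplot.zf_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$noise, y = .data$rel_rmse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "noise level", y = "relative RMSE") +
    ggplot2::theme_minimal()
}
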