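#' Periodic contraction waveform
#'
#' Dimensionless contraction phase `c(t)` of the simulated ventricle: 0 at
#' end-diastole, 1 at end-systole, periodic, continuous, with exactly one
#' maximum and one minimum per period. Each phase is a raised cosine, so the
#' waveform is differentiable everywhere and the systolic and diastolic
#' phases can have different durations (`systolic_fraction` of the period is
#' spent contracting, the remainder relaxing).
#'
#' Chamber dimensions interpolate linearly in `c(t)`:
#' `L(t) = L_ed - (L_ed - L_es) * c(t)`, and likewise for the diameter.
#'
#' @param t time(s) in seconds (vectorised).
#' @param period heart period in seconds (> 0).
#' @param systolic_fraction fraction of the cycle spent contracting,
#'   strictly between 0 and 1.
#' @return numeric vector in `[0, 1]`, same length as `t`.
#' @export
#' @examples
#' contraction_waveform(0, 1, 0.4)    # end-diastole
#' contraction_waveform(0.4, 1, 0.4)  # end-systole
contraction_waveform <- function(t, period, systolic_fraction = 0.4) {
  check_positive_scalar(period, "period")
  if (!is.numeric(systolic_fraction) || length(systolic_fraction) != 1L ||
      systolic_fraction <= 0 || systolic_fraction >= 1) {
    abort_invalid_parameter("`systolic_fraction` must lie strictly between 0 and 1.")
  }
  u <- (t / period) %% 1
  sf <- systolic_fraction
  ifelse(u < sf,
         (1 - cos(pi * u / sf)) / 2,
         (1 + cos(pi * (u - sf) / (1 - sf))) / 2)
}

#' Configuration for the synthetic beating-heart generator
#'
#' Defaults emulate a 48 hpf myl7:EGFP ventricle imaged laterally on a
#' light-sheet system: 100 frames at 50 fps, a ~2.2 Hz beat
#' (`heart_period = 0.45` s), end-diastolic length/diameter 120/60 um
#' contracting to 100/45 um, rendered as a filled ellipse (the 2-D
#' projection of a prolate spheroid), blurred by a Gaussian PSF, with
#' Poisson shot noise on signal plus background and additive Gaussian read
#' noise.
#'
#' @param image_height,image_width frame size in pixels.
#' @param pixel_size um per pixel.
#' @param frame_rate frames per second.
#' @param n_frames number of frames.
#' @param heart_period beat period in seconds.
#' @param L_ed,L_es end-diastolic / end-systolic chamber length, um.
#' @param D_ed,D_es end-diastolic / end-systolic chamber diameter, um.
#' @param systolic_fraction fraction of the cycle spent contracting.
#' @param orientation long-axis angle in radians (anticlockwise from the
#'   image x axis).
#' @param center chamber centre in um, `c(x, y)`; defaults to the image
#'   centre.
#' @param signal_level mean photons per pixel inside the chamber.
#' @param background_level mean background photons per pixel.
#' @param read_noise_sd standard deviation of additive Gaussian read noise,
#'   photons.
#' @param shot_noise apply Poisson shot noise? Disable (with
#'   `read_noise_sd = 0`) for the exact noiseless limit.
#' @param psf_sigma Gaussian PSF sigma in um (0 disables blurring).
#' @param render_atrium also render a second, smaller, non-contracting
#'   "atrium" ellipse beyond the apex, to exercise chamber selection.
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the seed.
#'
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(image_height = 160, image_width = 160,
                             pixel_size = 1.0, frame_rate = 50,
                             n_frames = 100, heart_period = 0.45,
                             L_ed = 120, L_es = 100, D_ed = 60, D_es = 45,
                             systolic_fraction = 0.4,
                             orientation = pi / 7,
                             center = NULL,
                             signal_level = 200, background_level = 20,
                             read_noise_sd = 3, shot_noise = TRUE,
                             psf_sigma = 1.5,
                             render_atrium = FALSE,
                             seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    pixel_size = pixel_size, frame_rate = frame_rate,
    n_frames = as.integer(n_frames), heart_period = heart_period,
    L_ed = L_ed, L_es = L_es, D_ed = D_ed, D_es = D_es,
    systolic_fraction = systolic_fraction, orientation = orientation,
    center = center %||% c(image_width * pixel_size / 2,
                           image_height * pixel_size / 2),
    signal_level = signal_level, background_level = background_level,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    psf_sigma = psf_sigma, render_atrium = isTRUE(render_atrium),
    seed = as.integer(seed)
  )
  for (nm in c("pixel_size", "frame_rate", "heart_period", "L_ed", "L_es",
               "D_ed", "D_es")) {
    check_positive_scalar(cfg[[nm]], nm)
  }
  if (cfg$L_es > cfg$L_ed || cfg$D_es > cfg$D_ed) {
    abort_invalid_parameter("Diastole must be the larger configuration: L_ed >= L_es and D_ed >= D_es.")
  }
  if (cfg$systolic_fraction <= 0 || cfg$systolic_fraction >= 1) {
    abort_invalid_parameter("`systolic_fraction` must lie strictly between 0 and 1.")
  }
  if (cfg$n_frames < 2L) abort_invalid_parameter("`n_frames` must be at least 2.")
  if (cfg$read_noise_sd < 0 || cfg$background_level < 0 || cfg$signal_level < 0) {
    abort_invalid_parameter("Noise and intensity levels must be non-negative.")
  }
  # The whole chamber (plus PSF skirt) must fit in the field of view:
  # a truncated chamber would corrupt every geometric measurement.
  ext <- ellipse_extent(cfg$L_ed / 2, cfg$D_ed / 2, cfg$orientation)
  margin <- 3 * cfg$psf_sigma + 2 * cfg$pixel_size
  fov <- c(cfg$image_width, cfg$image_height) * cfg$pixel_size
  lo <- cfg$center - ext - margin
  hi <- cfg$center + ext + margin
  if (cfg$render_atrium) {
    at <- atrium_spec(cfg)
    aext <- ellipse_extent(at$a, at$b, cfg$orientation)
    lo <- pmin(lo, at$center - aext - margin)
    hi <- pmax(hi, at$center + aext + margin)
  }
  if (any(lo < 0) || any(hi > fov)) {
    abort_invalid_parameter("Chamber ellipse (plus PSF margin) exceeds the field of view; enlarge the image or shrink the chamber.")
  }
  structure(cfg, class = "generator_config")
}

# Half-extent of a rotated ellipse along the image axes.
ellipse_extent <- function(a, b, theta) {
  c(sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

# Placement of the optional decoy atrium: beyond the venous pole along the
# long axis, 55% linear size of the diastolic ventricle, non-contracting.
atrium_spec <- function(cfg) {
  scale <- 0.55
  a <- scale * cfg$L_ed / 2
  b <- scale * cfg$D_ed / 2
  gap <- 0.15 * cfg$L_ed
  offset <- cfg$L_ed / 2 + gap + a
  dir <- c(cos(cfg$orientation), sin(cfg$orientation))
  list(a = a, b = b, center = cfg$center - offset * dir)
}

# Analytic filled-ellipse mask on the pixel grid (pixel-centre membership).
# Returns an H x W logical matrix; rows are y, columns are x.
ellipse_mask <- function(h, w, pixel_size, center, a, b, theta) {
  x <- (seq_len(w) - 0.5) * pixel_size
  y <- (seq_len(h) - 0.5) * pixel_size
  dx <- outer(rep(1, h), x) - center[1]
  dy <- outer(y, rep(1, w)) - center[2]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic beating-ventricle movie with exact ground truth
#'
#' Renders the ventricle in every frame as a filled ellipse whose length and
#' diameter follow [contraction_waveform()], convolves with a Gaussian PSF,
#' and applies the standard fluorescence camera noise model
#' (Poisson shot noise on signal + background, additive Gaussian read
#' noise). Bit-identical output for a given config (including seed).
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   * `movie`: a [movie_stack()];
#'   * `truth`: a `ground_truth` list holding the per-frame true `L`, `D`,
#'     area and prolate volume, the true end-diastole / end-systole frame
#'     indices, and the true per-fish parameters (EDV, ESV, SV, EF, FS,
#'     FAC, HR, CO).
#' @export
#' @examples
#' sim <- generate_beating_movie(generator_config(n_frames = 30, seed = 7))
#' sim$truth$params$EF_pct
generate_beating_movie <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  cfg <- config
  t <- (seq_len(cfg$n_frames) - 1) / cfg$frame_rate
  cc <- contraction_waveform(t, cfg$heart_period, cfg$systolic_fraction)
  L <- cfg$L_ed - (cfg$L_ed - cfg$L_es) * cc
  D <- cfg$D_ed - (cfg$D_ed - cfg$D_es) * cc

  h <- cfg$image_height; w <- cfg$image_width
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  at <- if (cfg$render_atrium) atrium_spec(cfg) else NULL

  frames <- withr::with_seed(cfg$seed, {
    arr <- array(0, dim = c(cfg$n_frames, h, w))
    for (i in seq_len(cfg$n_frames)) {
      mask <- ellipse_mask(h, w, cfg$pixel_size, cfg$center,
                           L[i] / 2, D[i] / 2, cfg$orientation)
      ideal <- cfg$background_level + cfg$signal_level * mask
      if (!is.null(at)) {
        amask <- ellipse_mask(h, w, cfg$pixel_size, at$center,
                              at$a, at$b, cfg$orientation)
        ideal <- ideal + cfg$signal_level * amask
      }
      if (sigma_px > 0) {
        ideal <- as.matrix(EBImage::gblur(ideal, sigma = sigma_px))
      }
      obs <- if (cfg$shot_noise) {
        matrix(rpois(h * w, lambda = pmax(ideal, 0)), h, w)
      } else ideal
      if (cfg$read_noise_sd > 0) {
        obs <- obs + matrix(rnorm(h * w, sd = cfg$read_noise_sd), h, w)
      }
      arr[i, , ] <- pmax(obs, 0)
    }
    arr
  })

  movie <- movie_stack(frames, pixel_size = cfg$pixel_size,
                       frame_rate = cfg$frame_rate,
                       id = sprintf("sim-seed%d", cfg$seed))

  per_frame <- tibble(
    frame = seq_len(cfg$n_frames),
    time_s = t,
    contraction = cc,
    length_um = L,
    diameter_um = D,
    area_um2 = pi * (L / 2) * (D / 2),
    volume_um3 = (pi / 6) * L * D^2
  )
  t_max <- t[cfg$n_frames]
  ed_times <- seq(0, t_max, by = cfg$heart_period)
  es0 <- cfg$systolic_fraction * cfg$heart_period
  es_times <- if (es0 > t_max) numeric(0) else seq(es0, t_max, by = cfg$heart_period)
  to_idx <- function(ts) unique(pmin(pmax(round(ts * cfg$frame_rate) + 1, 1),
                                     cfg$n_frames))
  EDV <- prolate_volume(cfg$L_ed, cfg$D_ed)
  ESV <- prolate_volume(cfg$L_es, cfg$D_es)
  HR <- 1 / cfg$heart_period
  params <- tibble(
    EDV_um3 = EDV, ESV_um3 = ESV, SV_um3 = EDV - ESV,
    EF_pct = (EDV - ESV) / EDV * 100,
    FS = (cfg$D_ed - cfg$D_es) / cfg$D_ed,
    FAC_pct = (cfg$L_ed * cfg$D_ed - cfg$L_es * cfg$D_es) /
      (cfg$L_ed * cfg$D_ed) * 100,
    HR_hz = HR,
    CO_um3_per_s = (EDV - ESV) * HR
  )
  truth <- structure(
    list(per_frame = per_frame, params = params,
         ed_frames = to_idx(ed_times), es_frames = to_idx(es_times),
         config = cfg),
    class = "ground_truth"
  )
  list(movie = movie, truth = truth)
}

#' Write a synthetic movie and its ground truth to disk
#'
#' The movie goes to a multi-page TIFF and the ground truth to a JSON
#' sidecar with the same basename and suffix `.truth.json`.
#'
#' @param sim a list as returned by [generate_beating_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(sim, path) {
  write_stack(sim$movie, path)
  sidecar <- sub("\\.[^.]*$", "", path)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    list(per_frame = truth$per_frame, params = truth$params,
         ed_frames = truth$ed_frames, es_frames = truth$es_frames,
         config = truth$config),
    paste0(sidecar, ".truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a phenotype cohort table with known per-group risk
#'
#' Each embryo is an independent Bernoulli draw of the small-ventricle (SV)
#' phenotype with its group's probability; the result is the usual
#' genotype-by-phenotype count table scored at 48 hpf.
#'
#' @param group_probs named numeric vector: probability of the SV phenotype
#'   per genotype group.
#' @param n_per_group embryos per group; scalar or vector matching
#'   `group_probs`.
#' @param seed integer RNG seed.
#' @return a tibble with columns `group`, `nv`, `sv`, `n`, `sv_prob`.
#' @export
#' @examples
#' generate_phenotype_cohort(c(wt = 0.02, mutant = 0.45), 60, seed = 1)
generate_phenotype_cohort <- function(group_probs, n_per_group, seed = 1L) {
  if (length(group_probs) == 0L) {
    abort_invalid_parameter("At least one group is required.")
  }
  if (is.null(names(group_probs)) || any(!nzchar(names(group_probs)))) {
    abort_invalid_parameter("`group_probs` must be a named vector.")
  }
  if (any(group_probs < 0 | group_probs > 1)) {
    abort_invalid_parameter("Probabilities must lie in [0, 1].")
  }
  n_per_group <- rep_len(as.integer(n_per_group), length(group_probs))
  if (any(n_per_group < 1L)) {
    abort_invalid_parameter("Each group needs at least one embryo.")
  }
  sv <- withr::with_seed(as.integer(seed), {
    mapply(function(n, p) rbinom(1L, n, p), n_per_group, group_probs)
  })
  tibble(
    group = names(group_probs),
    nv = n_per_group - sv,
    sv = as.integer(sv),
    n = n_per_group,
    sv_prob = unname(group_probs)
  )
}

#' Generate a gene-statistics table with labelled true differential expression
#'
#' Produces `(gene, log2FC, FDR)` rows for exercising the differential
#' expression filter. True-DE genes draw `|log2FC|` strictly above 0.4
#' (0.45 plus an exponential tail scaled by `lfc_scale`) and FDR uniformly
#' in `[0, 0.05]`; null genes draw log2FC from a tight normal around zero
#' and FDR uniformly in `[0, 1]`.
#'
#' @param n_genes number of genes (>= 1).
#' @param frac_de fraction of genes that are truly differentially
#'   expressed, in `[0, 1]`.
#' @param lfc_scale scale of the exponential tail added to the true-DE
#'   fold-change magnitude.
#' @param seed integer RNG seed.
#' @return a tibble with columns `gene`, `log2FC`, `FDR`, `true_de`.
#' @export
generate_gene_table <- function(n_genes, frac_de = 0.2, lfc_scale = 1,
                                seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) {
    abort_invalid_parameter("`n_genes` must be a positive integer.")
  }
  if (frac_de < 0 || frac_de > 1) {
    abort_invalid_parameter("`frac_de` must lie in [0, 1].")
  }
  withr::with_seed(as.integer(seed), {
    n_de <- round(n_genes * frac_de)
    true_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    lfc <- numeric(n_genes)
    fdr <- numeric(n_genes)
    if (n_de > 0) {
      mag <- 0.45 + stats::rexp(n_de, rate = 1 / lfc_scale)
      lfc[true_de] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
      fdr[true_de] <- runif(n_de, 0, 0.05)
    }
    if (n_de < n_genes) {
      lfc[!true_de] <- rnorm(n_genes - n_de, sd = 0.15)
      fdr[!true_de] <- runif(n_genes - n_de)
    }
    tibble(
      gene = sprintf("gene%05d", seq_len(n_genes)),
      log2FC = lfc, FDR = fdr, true_de = true_de
    )
  })
}
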