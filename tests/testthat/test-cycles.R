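geom_from_areas <- function(areas, flagged = rep(FALSE, length(areas))) {
  tibble::tibble(frame = seq_along(areas),
                 area_um2 = ifelse(flagged, NA_real_, areas),
                 flagged = flagged)
}

test_that("area trace interpolates flagged frames linearly", {
  g <- geom_from_areas(c(100, 100, 200), flagged = c(FALSE, TRUE, FALSE))
  tr <- area_trace(g)
  expect_equal(as.numeric(tr), c(100, 150, 200))
  expect_equal(attr(tr, "n_interpolated"), 1L)
  const <- area_trace(geom_from_areas(rep(5, 10)))
  expect_equal(as.numeric(const), rep(5, 10))
  expect_error(area_trace(geom_from_areas(c(1, 2), flagged = c(TRUE, TRUE))),
               class = "zfcardio_cycle_error")
})

test_that("extrema of a pure sinusoid are found at the analytic phase", {
  n <- 100; fps <- 50
  tr <- 1000 + 100 * cos(2 * pi * (0:(n - 1)) / 20)  # 5 periods, max at 0
  cs <- detect_extrema(tr, fps)
  expect_length(cs$ed_frames, 6)  # maxima at frames 1,21,...,81 plus end
  true_ed <- seq(1, 101, by = 20)
  expect_true(all(vapply(cs$ed_frames,
                         function(f) min(abs(f - true_ed)), 0) <= 1))
  true_es <- seq(11, 91, by = 20)
  expect_length(cs$es_frames, 5)
  expect_true(all(vapply(cs$es_frames,
                         function(f) min(abs(f - true_es)), 0) <= 1))
  # alternation and pairing invariants
  merged <- sort(c(cs$ed_frames, cs$es_frames))
  types <- ifelse(merged %in% cs$ed_frames, "ed", "es")
  expect_true(all(types[-1] != types[-length(types)]))
  expect_true(all(tr[cs$pairs$ed] > tr[cs$pairs$es]))
})

test_that("aperiodic traces are rejected", {
  expect_error(detect_extrema(seq(1, 100), 50), class = "zfcardio_cycle_error")
  expect_error(detect_extrema(rep(3, 50), 50), class = "zfcardio_cycle_error")
})

test_that("sub-threshold noise moves extrema by at most one frame", {
  n <- 150
  tr <- 1000 + 100 * cos(2 * pi * (0:(n - 1)) / 25)
  clean <- detect_extrema(tr, 50)
  noisy <- withr::with_seed(42, tr + runif(n, -4, 4))  # 2% of range
  cs <- detect_extrema(noisy, 50)
  expect_equal(length(cs$ed_frames), length(clean$ed_frames))
  shift <- vapply(cs$ed_frames,
                  function(f) min(abs(f - clean$ed_frames)), 0)
  expect_true(all(shift <= 1))
})

test_that("the synthetic default movie yields all cycles within one frame", {
  cfg <- generator_config(seed = 19)
  sim <- generate_beating_movie(cfg)
  ms <- segment_stack(sim$movie)
  tr <- area_trace(stack_geometry(ms, cfg$pixel_size))
  cs <- detect_extrema(tr, cfg$frame_rate)
  expect_gte(nrow(cs$pairs), 3)
  expect_true(all(vapply(cs$ed_frames,
                         function(f) min(abs(f - sim$truth$ed_frames)), 0) <= 1))
  expect_true(all(vapply(cs$es_frames,
                         function(f) min(abs(f - sim$truth$es_frames)), 0) <= 1))
})

test_that("heart rate is complete cycles over acquisition time", {
  cs5 <- cycle_set(ed_frames = seq(1, 101, by = 20),
                   es_frames = seq(11, 111, by = 20),
                   acquisition_time = 2.0)
  expect_equal(heart_rate(cs5), 2.5)  # 5 ED-to-ED intervals in 2 s
  cs1 <- cycle_set(ed_frames = c(1, 26), es_frames = 13,
                   acquisition_time = 0.5)
  expect_equal(heart_rate(cs1), 2.0)
  cs0 <- cycle_set(ed_frames = 5, es_frames = 15, acquisition_time = 1)
  expect_error(heart_rate(cs0), class = "zfcardio_cycle_error")
})

test_that("recovered heart rate approximates the generator period", {
  cfg <- generator_config(seed = 29)
  sim <- generate_beating_movie(cfg)
  res <- quiet_run_fish(sim$movie)
  # the ED-to-ED cycle count is integer, so the error bound (one part in
  # ten at 4 full cycles per record) can be attained exactly
  expect_lte(abs(res$params$HR_hz / (1 / cfg$heart_period) - 1), 0.10 + 1e-9)
})

test_that("heart rate ignores intensity scale", {
  sim <- generate_beating_movie(small_config(seed = 37))
  bright <- sim$movie
  bright$frames <- bright$frames * 4
  a <- quiet_run_fish(sim$movie)
  b <- quiet_run_fish(bright)
  expect_equal(a$params$HR_hz, b$params$HR_hz)
})

test_that("cycle sets expose tidy and glance summaries", {
  tr <- 100 + 10 * cos(2 * pi * (0:99) / 20)
  cs <- detect_extrema(tr, 50)
  td <- tidy(cs)
  expect_true(all(c("frame", "type", "area_um2") %in% names(td)))
  expect_equal(nrow(td), length(cs$ed_frames) + length(cs$es_frames))
  gl <- glance(cs)
  expect_equal(gl$n_pairs, nrow(cs$pairs))
  expect_equal(gl$hr_hz, heart_rate(cs))
  expect_s3_class(ggplot2::autoplot(cs), "ggplot")
})
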