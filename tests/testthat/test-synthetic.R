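test_that("contraction waveform is anchored at end-diastole and end-systole", {
  expect_equal(contraction_waveform(0, 1.0, 0.4), 0)
  expect_equal(contraction_waveform(0.4, 1.0, 0.4), 1)
  # periodicity: anchors recur every period
  expect_equal(contraction_waveform(c(1, 2, 2.4), 1.0, 0.4), c(0, 0, 1))
  expect_error(contraction_waveform(0, -1, 0.4), class = "zfcardio_invalid_parameter")
  expect_error(contraction_waveform(0, 1, 1.2), class = "zfcardio_invalid_parameter")
})

test_that("waveform has exactly one maximum and one minimum per period", {
  t <- seq(0, 3, by = 1e-3)
  cc <- contraction_waveform(t, 1.0, 0.4)
  expect_true(all(cc >= 0 & cc <= 1))
  peaks <- which(diff(sign(diff(cc))) < 0) + 1
  troughs <- which(diff(sign(diff(cc))) > 0) + 1
  expect_length(peaks, 3)   # t in [0, 3): three systolic peaks
  expect_length(troughs, 2) # interior minima between them
  # continuity across the systole/diastole junction
  expect_lt(max(abs(diff(cc))), 5e-3)
})

test_that("ground truth satisfies the chamber-equation invariants", {
  sim <- generate_beating_movie(small_config(n_frames = 40, seed = 11))
  tr <- sim$truth
  expect_equal(tr$per_frame$volume_um3,
               (pi / 6) * tr$per_frame$length_um * tr$per_frame$diameter_um^2)
  expect_gt(tr$params$EF_pct, 0); expect_lt(tr$params$EF_pct, 100)
  expect_equal(tr$params$SV_um3, tr$params$EDV_um3 - tr$params$ESV_um3)
  expect_equal(tr$params$CO_um3_per_s, tr$params$SV_um3 * tr$params$HR_hz)
})

test_that("ground-truth EF matches the hand-evaluated prolate ratio", {
  # (1 - (100 * 45^2) / (120 * 60^2)) * 100; pi/6 cancels
  sim <- generate_beating_movie(
    generator_config(L_ed = 120, L_es = 100, D_ed = 60, D_es = 45,
                     n_frames = 10, seed = 1))
  expect_equal(sim$truth$params$EF_pct, 53.125)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config(n_frames = 12, seed = 99)
  a <- generate_beating_movie(cfg)
  b <- generate_beating_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$per_frame, b$truth$per_frame)
})

test_that("noiseless frames threshold to the analytic ellipse mask", {
  cfg <- generator_config(shot_noise = FALSE, read_noise_sd = 0,
                          n_frames = 4, seed = 5)
  sim <- generate_beating_movie(cfg)
  for (i in c(1L, 4L)) {
    m <- segment_frame(sim$movie$frames[i, , ])
    expect_gte(iou(m, truth_mask(cfg, sim$truth, i)), 0.99)
  }
})

test_that("an ellipse exceeding the field of view is rejected", {
  expect_error(generator_config(image_height = 80, image_width = 80),
               class = "zfcardio_invalid_parameter")
})

test_that("rendered chamber area matches the analytic ellipse within 2%", {
  cfg <- small_config(shot_noise = FALSE, read_noise_sd = 0,
                      n_frames = 4, seed = 2)
  sim <- generate_beating_movie(cfg)
  for (i in c(1L, 3L)) {
    m <- segment_frame(sim$movie$frames[i, , ])
    a_px <- sum(m) * cfg$pixel_size^2
    expect_lt(abs(a_px / sim$truth$per_frame$area_um2[i] - 1), 0.02)
  }
})

test_that("two seeds with the same config differ only in noise", {
  a <- generate_beating_movie(small_config(n_frames = 10, seed = 1))
  b <- generate_beating_movie(small_config(n_frames = 10, seed = 2))
  expect_false(identical(a$movie$frames, b$movie$frames))
  area_a <- sum(segment_frame(a$movie$frames[1, , ]))
  area_b <- sum(segment_frame(b$movie$frames[1, , ]))
  expect_lt(abs(area_a / area_b - 1), 0.05)
})

test_that("the optional atrium is rendered and the ventricle still selected", {
  cfg <- generator_config(image_height = 240, image_width = 240,
                          center = c(150, 150),
                          render_atrium = TRUE, n_frames = 4, seed = 3)
  sim <- generate_beating_movie(cfg)
  raw <- segment_frame(sim$movie$frames[1, , ])
  comp <- EBImage::bwlabel(EBImage::Image(raw * 1))
  expect_gte(max(comp), 2)  # two chambers present
  sel <- select_ventricle_component(raw, "largest")
  expect_gte(iou(sel, truth_mask(cfg, sim$truth, 1)), 0.95)
})

test_that("phenotype cohorts honour the group probabilities", {
  tab <- generate_phenotype_cohort(c(wt = 0, mut = 1), 25, seed = 4)
  expect_equal(tab$sv, c(0L, 25L))
  expect_equal(tab$nv, c(25L, 0L))
  big <- generate_phenotype_cohort(c(g = 0.5), 10000, seed = 8)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(big$sv / big$n - 0.5), 3 * se)
  expect_identical(generate_phenotype_cohort(c(a = .3, b = .7), 10, seed = 1),
                   generate_phenotype_cohort(c(a = .3, b = .7), 10, seed = 1))
  expect_error(generate_phenotype_cohort(numeric(0), 10),
               class = "zfcardio_invalid_parameter")
  expect_error(generate_phenotype_cohort(c(a = 1.5), 10),
               class = "zfcardio_invalid_parameter")
})

test_that("gene tables give the DEG filter known truth", {
  null_tab <- generate_gene_table(2000, frac_de = 0, seed = 3)
  hits <- filter_degs(null_tab)
  # null genes pass only by the joint accident FDR<=.05 and |lfc|>.4
  expect_lt(nrow(hits) / nrow(null_tab), 0.01)
  all_de <- generate_gene_table(500, frac_de = 1, lfc_scale = 1, seed = 3)
  expect_equal(nrow(filter_degs(all_de)), 500L)
  mixed <- generate_gene_table(1000, frac_de = 0.2, seed = 5)
  got <- filter_degs(mixed)
  recall <- mean(mixed$gene[mixed$true_de] %in% got$gene)
  expect_gte(recall, 0.95)
  expect_error(generate_gene_table(0), class = "zfcardio_invalid_parameter")
})
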