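# Shared fixtures: analytic masks and small generator configs, built in code.

# Filled-ellipse mask by pixel-centre membership (independent of the
# generator's internal renderer: reimplemented here on purpose so tests
# compare two routes to the same shape).
make_ellipse_mask <- function(h, w, center_rc, a_px, b_px, theta = 0) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - center_rc[1]
  dx <- cols - center_rc[2]
  # theta measured from the column (x) axis, anticlockwise
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Analytic ground-truth mask for a generator config at frame i.
truth_mask <- function(cfg, truth, i) {
  L <- truth$per_frame$length_um[i]
  D <- truth$per_frame$diameter_um[i]
  make_ellipse_mask(cfg$image_height, cfg$image_width,
                    c(cfg$center[2] / cfg$pixel_size + 0.5,
                      cfg$center[1] / cfg$pixel_size + 0.5),
                    (L / 2) / cfg$pixel_size, (D / 2) / cfg$pixel_size,
                    cfg$orientation)
}

# Smaller, faster generator config for tests that only need plumbing.
small_config <- function(...) {
  generator_config(image_height = 120, image_width = 120,
                   L_ed = 70, L_es = 58, D_ed = 40, D_es = 30, ...)
}

quiet_run_fish <- function(...) suppressMessages(run_fish(...))
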