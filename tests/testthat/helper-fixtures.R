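# Shared fixtures: everything is generated in code, no stored data.

# A small scene raster used by most tests (1/10 of the analysis space).
test_raster <- c(128, 102)

test_scenes <- function(n = 3, raster = test_raster, seed0 = 100) {
  lapply(seq_len(n), function(i) make_scene(raster = raster, seed = seed0 + i))
}

# Per-subject maps built as ground truth + i.i.d. Gaussian noise, for
# reliability tests (truth: a scene's saliency).
noisy_cohort <- function(truth, n_subjects, noise_sd, seed) {
  digitrack:::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      g <- pmax(truth + matrix(rnorm(length(truth), 0, noise_sd),
                               nrow(truth)), 0)
      attention_map(g, image_id = "noisy")
    })
  })
}

# Digit explorer config scaled to the test raster (x1/10 of the tablet
# arithmetic: 1000 px/s over 4000 px on a 1280-wide analysis space).
digit_cfg_scaled <- function(raster = test_raster, dwell_s = 0.25) {
  f <- raster[1] / 1280
  explorer_config("digit", speed_px_s = 1000 * f,
                  path_threshold_px = 4000 * f, dwell_s = dwell_s)
}

# Brute-force KDE oracle: per-pixel double sum.
kde_brute_force <- function(x, y, w, h_bw, raster) {
  out <- matrix(0, raster[2], raster[1])
  for (r in seq_len(raster[2])) {
    for (cc in seq_len(raster[1])) {
      out[r, cc] <- sum(w * exp(-((cc - 1 - x)^2 + (r - 1 - y)^2) /
                                  (2 * h_bw^2)))
    }
  }
  out / max(out)
}
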