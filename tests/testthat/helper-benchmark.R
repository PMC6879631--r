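# Scaled-down clinical benchmark world (fixed before any outcome was
# measured): 1/10 analysis raster, 4 scenes, 10 reference + 22 vs 22 test
# subjects, jitter and KDE bandwidth scaled with the raster.
bench_raster <- c(128, 102)
bench_bw <- 3          # 30 px at 1280 -> 3 px at 128
bench_jitter <- 4      # 8 px at 256 -> 4 px at 128

bench_scenes <- function(seed0 = 100) {
  lapply(1:4, function(i) make_scene(raster = bench_raster, seed = seed0 + i))
}

# One 22-vs-22 replicate: returns the neurotypicality scores data.frame.
bench_scores <- function(mode, seed, scenes) {
  cfg <- if (mode == "eye") {
    explorer_config("eye")
  } else {
    explorer_config("digit", speed_px_s = 100, path_threshold_px = 400,
                    dwell_s = 0.25)
  }
  pop <- make_population(
    list(ref = profile_neurotypical(n_subjects = 10, jitter_px = bench_jitter),
         ctrl = profile_neurotypical(n_subjects = 22, jitter_px = bench_jitter),
         asd = profile_eyes_avoidant(n_subjects = 22, jitter_px = bench_jitter)),
    scenes, cfg, seed = seed)
  run_pipeline(pop, list(raster = bench_raster, bandwidth_px = bench_bw,
                         reference_group = "ref", reference_n = 10))$scores
}

bench_auc <- function(scores) {
  ctrl <- scores$score[scores$group == "ctrl"]
  asd <- scores$score[scores$group == "asd"]
  g <- seq(min(scores$score) - 2.4, max(scores$score) + 2.4,
           length.out = 512)
  roc_from_densities(fit_score_density(ctrl, grid = g),
                     fit_score_density(asd, grid = g))$auc
}
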