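test_that("make_scene builds channels whose weighted sum is the saliency", {
  sc <- make_scene(raster = c(64, 52), seed = 12)
  recon <- matrix(0, 52, 64)
  for (r in sc$roles) recon <- recon + sc$mixture[r] * sc$channels[, , r]
  expect_equal(recon / sc$mixture_scale, sc$saliency, tolerance = 1e-12)
  expect_equal(max(sc$saliency), 1)
  expect_true(all(dim(sc$image) == c(52, 64)))

  # one blob: saliency peak of 1 at the blob centre
  one <- make_scene(raster = c(40, 40),
                    blobs = data.frame(role = "object", x = 10, y = 30,
                                       sigma = 4),
                    mixture = c(object = 1), seed = 1)
  expect_equal(one$saliency[31, 11], 1)
  expect_equal(which(one$saliency == 1), 31 + 10 * 40)

  # two equal blobs: two equal unit peaks (symmetry)
  two <- make_scene(raster = c(41, 21),
                    blobs = data.frame(role = c("object", "object"),
                                       x = c(10, 30), y = c(10, 10),
                                       sigma = c(3, 3)),
                    mixture = c(object = 1), seed = 1)
  expect_equal(two$saliency[11, 11], two$saliency[11, 31], tolerance = 1e-9)
  expect_equal(max(two$saliency), 1)
  # scenes are deterministic per seed
  expect_equal(make_scene(raster = c(64, 52), seed = 12)$saliency,
               sc$saliency)
})

test_that("subject_saliency applies mass-fraction preferences and bias", {
  sc <- make_scene(raster = c(64, 52), seed = 13)
  prof <- profile_neurotypical()
  p <- subject_saliency(sc, prof)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # with spatially disjoint channels, mass shares equal the normalised
  # preference weights
  disj <- make_scene(raster = c(90, 30),
                     blobs = data.frame(role = c("eyes", "face", "object"),
                                        x = c(15, 45, 75), y = c(15, 15, 15),
                                        sigma = c(2, 2, 2)),
                     mixture = c(eyes = 1, face = 1, object = 1), seed = 1)
  pd <- subject_saliency(disj, population_profile(
    preferences = c(eyes = 1, face = 0.6, object = 0.4)))
  expect_equal(sum(pd[, 1:30]), 1 / 2, tolerance = 1e-3)
  expect_equal(sum(pd[, 31:60]), 0.6 / 2, tolerance = 1e-3)
  expect_equal(sum(pd[, 61:90]), 0.4 / 2, tolerance = 1e-3)
  # lateral bias: exact right-of-midline mass
  neg <- profile_left_neglect(lateral_bias = 0.85)
  pn <- subject_saliency(sc, neg)
  right_cols <- (seq_len(64) - 1) > 32
  expect_equal(sum(pn[, right_cols]), 0.85, tolerance = 1e-12)
})

test_that("eye simulator: determinism, bounds, and convergence to the truth", {
  sc <- make_scene(raster = c(64, 52), seed = 14)
  prof <- profile_neurotypical(jitter_px = 2)
  f1 <- simulate_eye_subject(sc, prof, seed = 5)
  f2 <- simulate_eye_subject(sc, prof, seed = 5)
  expect_identical(f1$x_px, f2$x_px)
  expect_identical(f1$duration_ms, f2$duration_ms)
  expect_true(all(f1$x_px >= 0 & f1$x_px <= 63))
  expect_true(all(f1$y_px >= 0 & f1$y_px <= 51))
  # total duration reaches the trial length
  expect_gte(sum(f1$duration_ms) / 1000, 4)

  # zero jitter, single-peak saliency: all fixations at the peak
  one <- make_scene(raster = c(40, 40),
                    blobs = data.frame(role = "object", x = 20, y = 20,
                                       sigma = 0.6),
                    mixture = c(object = 1), seed = 1)
  prof0 <- population_profile(preferences = c(object = 1), jitter_px = 0)
  f0 <- simulate_eye_subject(one, prof0, seed = 2)
  expect_true(all(abs(f0$x_px - 20) <= 2 & abs(f0$y_px - 20) <= 2))

  # empirical density over 200 subjects ~ generating density (no jitter)
  prof_nj <- profile_neurotypical(jitter_px = 0)
  maps <- lapply(1:200, function(s)
    map_from_fixations(simulate_eye_subject(sc, prof_nj, seed = s),
                       bandwidth_px = 1.5, raster = c(64, 52)))
  g <- group_map(maps)
  truth <- subject_saliency(sc, prof_nj)
  expect_gt(cor(as.vector(g$grid), as.vector(truth)), 0.95)
})

test_that("digit simulator: stopping rule, duration arithmetic, determinism", {
  sc <- make_scene(raster = c(1280, 1024), seed = 15)
  prof <- profile_neurotypical(jitter_px = 30)
  cfg <- explorer_config("digit")  # 1000 px/s, 4000 px, dwell 0
  tr <- simulate_digit_subject(sc, prof, cfg, seed = 6)
  expect_gte(path_length(tr), 4000)
  expect_false(tr$under_threshold)
  # duration ~ threshold / speed = 4 s (chord-sampling slack < 2%)
  expect_lt(abs(diff(range(tr$t_s)) - 4), 0.08)
  expect_identical(simulate_digit_subject(sc, prof, cfg, seed = 6)$x_px,
                   tr$x_px)
  expect_true(all(tr$x_px >= 0 & tr$x_px <= 1279))

  # group KDE of many digit subjects tracks the (smoothing-matched) truth
  scs <- make_scene(raster = c(128, 102), seed = 301)
  profs <- profile_neurotypical(jitter_px = 4)
  dmaps <- lapply(1:120, function(s) map_from_trajectory(
    simulate_digit_subject(scs, profs, digit_cfg_scaled(), seed = s),
    bandwidth_px = 3, raster = c(128, 102)))
  g <- group_map(dmaps)$grid
  smoothed <- digitrack:::blur_matrix(subject_saliency(scs, profs), 5)
  expect_gt(cor(as.vector(g), as.vector(smoothed)), 0.9)
})

test_that("make_population emits a consistent, deterministic dataset", {
  scenes <- test_scenes(2, raster = c(64, 52), seed0 = 400)
  profs <- list(ctrl = profile_neurotypical(n_subjects = 3, jitter_px = 2),
                asd = profile_eyes_avoidant(n_subjects = 2, jitter_px = 2))
  pop <- make_population(profs, scenes, explorer_config("eye"), seed = 9)
  expect_equal(nrow(pop$manifest), (3 + 2) * 2)
  expect_length(pop$records, nrow(pop$manifest))
  expect_setequal(unique(pop$manifest$group), c("ctrl", "asd"))
  pop2 <- make_population(profs, scenes, explorer_config("eye"), seed = 9)
  expect_identical(pop$records[[7]]$x_px, pop2$records[[7]]$x_px)

  # empty population: valid empty manifest
  none <- make_population(list(x = profile_neurotypical(n_subjects = 0)),
                          scenes, explorer_config("eye"), seed = 1)
  expect_identical(nrow(none$manifest), 0L)
  expect_length(none$records, 0)
})

test_that("effect-size dial: group gap grows with the preference gap", {
  scenes <- test_scenes(2, raster = c(64, 52), seed0 = 500)
  gap_for <- function(eyes_pref) {
    av <- population_profile(preferences = c(eyes = eyes_pref, face = 0.9,
                                             object = 0.5,
                                             background = 0.05),
                             jitter_px = 2, n_subjects = 6)
    ct <- profile_neurotypical(n_subjects = 6, jitter_px = 2)
    pop <- make_population(list(ctrl = ct, avoid = av), scenes,
                           explorer_config("eye"), seed = 31)
    res <- run_pipeline(pop, list(raster = c(64, 52), bandwidth_px = 2))
    # mean eye-channel exploration share difference, via map correlation
    # with the eyes channel truth
    eyemap <- attention_map(scenes[[1]]$channels[, , "eyes"])
    ec <- function(grp) mean(sapply(
      pop$manifest$subject_id[pop$manifest$group == grp][1:6], function(s)
        map_correlation(res$maps[[paste(s, scenes[[1]]$image_id,
                                        sep = "|")]], eyemap)))
    ec("ctrl") - ec("avoid")
  }
  gaps <- sapply(c(0.8, 0.4, 0.05), gap_for)
  expect_true(all(diff(gaps) > 0))
})

test_that("wCorr separates eyes-avoidant from neurotypical signatures", {
  scenes <- test_scenes(3, raster = c(64, 52), seed0 = 600)
  stacks <- lapply(scenes, function(s) make_feature_bank(s, K = 8, seed = 77))
  sig_for <- function(prof, seed0) {
    targets <- lapply(seq_along(scenes), function(i)
      map_from_fixations(simulate_eye_subject(scenes[[i]], prof,
                                              seed = seed0 + i),
                         bandwidth_px = 2, raster = c(64, 52)))
    suppressWarnings(learn_weights_wcorr(stacks, targets))
  }
  ctrl <- lapply(1:8, function(s)
    sig_for(profile_neurotypical(jitter_px = 2), 1000 + 10 * s))
  avoid <- lapply(1:8, function(s)
    sig_for(profile_eyes_avoidant(jitter_px = 2), 5000 + 10 * s))
  # eyes channel is channel 1 of the bank; its weight drops in avoiders
  r <- compare_channel_weights(ctrl, avoid, channel = 1)
  expect_lt(r$p_value, 0.01)
  expect_gt(mean(sapply(ctrl, function(w) w$weights[1])),
            mean(sapply(avoid, function(w) w$weights[1])))
})
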