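test_that("bilinear resize is exact on affine fields and stable round-trip", {
  # constant channel stays constant
  cstack <- feature_stack(array(0.4, c(10, 12, 2)))
  out <- resize_feature_maps(cstack, c(30, 24))
  expect_equal(out$maps[, , 1], matrix(0.4, 24, 30), tolerance = 1e-12)

  # 2x upsample of a linear ramp is a linear ramp
  ramp <- outer(seq(0, 1, length.out = 11), seq(0, 2, length.out = 13), `+`)
  up <- digitrack:::bilinear_resize(ramp, c(25, 21))
  oracle <- outer(seq(0, 1, length.out = 21), seq(0, 2, length.out = 25), `+`)
  expect_equal(up, oracle, tolerance = 1e-12)

  # down-up round trip of a smooth blob keeps correlation > 0.99
  sc <- make_scene(raster = c(64, 52), seed = 9)
  blob <- sc$saliency
  down <- digitrack:::bilinear_resize(blob, c(32, 26))
  back <- digitrack:::bilinear_resize(down, c(64, 52))
  expect_gt(cor(as.vector(back), as.vector(blob)), 0.99)
  expect_error(resize_feature_maps(cstack, c(0, 5)), "degenerate")
})

test_that("wCorr weights are mean channel-target correlations", {
  ds <- make_recovery_dataset(n_images = 4, K = 6, snr = 100,
                              raster = c(48, 48), seed = 5)
  # target identical to channel j -> weight_j = 1; complement -> -1
  stacks <- ds$stacks
  t_same <- lapply(stacks, function(s)
    attention_map(s$maps[, , 3], image_id = s$image_id))
  w <- learn_weights_wcorr(stacks, t_same)
  expect_equal(w$weights[3], 1, tolerance = 1e-9)
  expect_true(all(w$weights >= -1 - 1e-12 & w$weights <= 1 + 1e-12))
  t_neg <- lapply(stacks, function(s)
    attention_map(max(s$maps[, , 3]) - s$maps[, , 3], image_id = s$image_id))
  expect_equal(learn_weights_wcorr(stacks, t_neg)$weights[3], -1,
               tolerance = 1e-9)

  # equals the explicit per-image correlation average
  w2 <- learn_weights_wcorr(stacks, ds$targets)
  oracle <- rowMeans(sapply(seq_along(stacks), function(i) {
    sapply(1:6, function(k) cor(as.vector(stacks[[i]]$maps[, , k]),
                                as.vector(ds$targets[[i]]$grid)))
  }))
  expect_equal(w2$weights, oracle, tolerance = 1e-12)

  # invariant to affine rescaling of targets
  t_scaled <- lapply(ds$targets, function(t) attention_map(0.3 * t$grid))
  expect_equal(learn_weights_wcorr(stacks, t_scaled)$weights, w2$weights,
               tolerance = 1e-12)
})

test_that("wCorr recovers the generating ranking on noisy mixtures", {
  # independent channels (no overlapping semantic maps) for clean recovery
  ds <- make_recovery_dataset(n_images = 12, K = 8, snr = 5,
                              raster = c(48, 48), seed = 23,
                              include_roles = FALSE)
  w <- learn_weights_wcorr(ds$stacks, ds$targets)
  expect_gt(cor(w$weights, ds$weights, method = "spearman"), 0.9)
  # top learned channel is the generating top channel
  expect_identical(rank_channels(w)[1], which.max(ds$weights))
})

test_that("regression learner: least-squares limit and sparsity recovery", {
  # K = 1 exact linear relation, zero regularisation: slope recovered
  sc <- make_scene(raster = c(32, 32), seed = 3)
  st <- feature_stack(array(sc$saliency, c(32, 32, 1)))
  tg <- attention_map(0.6 * sc$saliency + 0.1)
  w <- learn_weights_regression(list(st), list(tg), lambda = 0)
  # unity normalisation rescaled the target by 1/max(0.6 s + 0.1)
  expect_equal(w$weights[1], 0.6 / max(0.6 * sc$saliency + 0.1),
               tolerance = 1e-6)

  # single informative channel among noise: near-zero weights elsewhere
  ds <- make_recovery_dataset(n_images = 6, K = 6, snr = 20,
                              weights = c(1, 0, 0, 0, 0, 0),
                              raster = c(48, 48), seed = 29)
  wr <- learn_weights_regression(ds$stacks, ds$targets, n_folds = 5)
  expect_gt(abs(wr$weights[1]), 10 * max(abs(wr$weights[-1])))
})

test_that("predict_saliency is the (normalised) weighted channel sum", {
  ds <- make_recovery_dataset(n_images = 2, K = 5, snr = 10,
                              raster = c(40, 40), seed = 31)
  st <- ds$stacks[[1]]
  w <- weight_vector(c(0.2, -0.4, 1.1, 0, 0.3))
  pred <- predict_saliency(st, w)
  raw <- matrix(0, 40, 40)
  for (k in 1:5) raw <- raw + w$weights[k] * st$maps[, , k]
  if (min(raw) < 0) raw <- raw - min(raw)
  expect_equal(pred$grid, raw / max(raw), tolerance = 1e-12)

  # one-hot -> normalised channel; zero weights -> flagged constant
  ph <- predict_saliency(st, weight_vector(c(0, 0, 1, 0, 0)))
  expect_equal(ph$grid, st$maps[, , 3] / max(st$maps[, , 3]),
               tolerance = 1e-12)
  expect_true(predict_saliency(st, weight_vector(rep(0, 5)))$constant)
  expect_error(predict_saliency(st, weight_vector(1:3)), "mismatch")
})

test_that("LOO cross-validation matches a hand-rolled loop and null is ~0", {
  ds <- make_recovery_dataset(n_images = 6, K = 5, snr = 8,
                              raster = c(40, 40), seed = 37)
  cc <- loo_cross_validate(ds$stacks, ds$targets, learner = "wcorr")
  oracle <- sapply(1:6, function(i) {
    w <- learn_weights_wcorr(ds$stacks[-i], ds$targets[-i])
    p <- predict_saliency(ds$stacks[[i]], w)
    cor(as.vector(p$grid), as.vector(ds$targets[[i]]$grid))
  })
  expect_equal(cc, oracle, tolerance = 1e-12)

  # targets equal to one channel: near-perfect CC on every fold (other
  # channels carry small sample correlations, so exactly 1 needs an
  # orthogonal bank)
  t_same <- lapply(ds$stacks, function(s) attention_map(s$maps[, , 2]))
  expect_true(all(loo_cross_validate(ds$stacks, t_same,
                                     learner = "wcorr") > 0.95))

  # targets independent of all channels -> mean CC near 0
  set.seed(43)
  t_null <- lapply(1:6, function(i)
    attention_map(digitrack:::blur_matrix(matrix(rnorm(1600), 40), 3) + 10))
  cc_null <- loo_cross_validate(ds$stacks, t_null, learner = "wcorr")
  expect_lt(abs(mean(cc_null)), 0.25)

  # LOO CC rises with SNR
  means <- sapply(c(0.5, 2, 10), function(snr) {
    d <- make_recovery_dataset(n_images = 6, K = 5, snr = snr,
                               raster = c(40, 40), seed = 41)
    mean(loo_cross_validate(d$stacks, d$targets, learner = "wcorr"))
  })
  expect_true(all(diff(means) > 0))
})

test_that("lasso and wCorr give comparable held-out prediction quality", {
  ds <- make_recovery_dataset(n_images = 8, K = 6, snr = 5,
                              raster = c(40, 40), seed = 47)
  cc_w <- mean(loo_cross_validate(ds$stacks, ds$targets, learner = "wcorr"))
  cc_r <- mean(loo_cross_validate(ds$stacks, ds$targets,
                                  learner = "regression", n_folds = 5),
               na.rm = TRUE)
  expect_gte(cc_r, cc_w - 0.05)
})

test_that("rank_channels sorts by weight with deterministic tie-breaks", {
  expect_identical(rank_channels(weight_vector(c(0.2, 0.9, -0.3))),
                   c(2L, 1L, 3L))
  expect_identical(rank_channels(weight_vector(rep(0.5, 4))), 1:4)
  expect_identical(rank_channels(weight_vector(c(1, 2, 2, 0))),
                   c(2L, 3L, 1L, 4L))
})

test_that("most_responsive_pixels keeps the top quantile", {
  ds <- make_recovery_dataset(n_images = 3, K = 4, snr = 10,
                              raster = c(40, 40), seed = 53)
  masks <- most_responsive_pixels(ds$stacks, channel = 2, top_fraction = 1)
  expect_true(all(sapply(masks, all)))
  # hot-blob channel, small fraction: mask sits inside the blob
  sc <- make_scene(raster = c(64, 52), seed = 4)
  hot <- digitrack:::gaussian_blob(c(64, 52), 20, 25, 5)
  st <- feature_stack(array(hot, c(52, 64, 1)))
  m <- most_responsive_pixels(list(st), 1, 0.01)[[1]]
  ij <- which(m, arr.ind = TRUE)
  expect_true(all(sqrt((ij[, 2] - 21)^2 + (ij[, 1] - 26)^2) < 8))
  # area fraction within one pixel-quantile step
  frac <- 0.1
  m2 <- most_responsive_pixels(list(ds$stacks[[1]]), 3, frac)[[1]]
  expect_lt(abs(mean(m2) - frac), 2 / length(m2) + 1e-3)
})

test_that("top_channel_match_pvalue is 1/K", {
  expect_identical(top_channel_match_pvalue(256), 1 / 256)
  expect_lt(top_channel_match_pvalue(256), 0.004)
  expect_identical(top_channel_match_pvalue(1), 1)
  expect_identical(top_channel_match_pvalue(2), 0.5)
})

test_that("compare_channel_weights: rank-sum with Bonferroni correction", {
  mk <- function(vals) lapply(vals, function(v) weight_vector(c(v, 0)))
  set.seed(59)
  a <- rnorm(22)
  same <- compare_channel_weights(mk(a), mk(a), channel = 1)
  expect_gt(same$p_uncorrected, 0.9)
  # Bonferroni: multiply by m, cap at 1
  r <- compare_channel_weights(mk(a), mk(a + 0.2), channel = 1, n_tested = 5)
  expect_equal(r$p_value, min(1, r$p_uncorrected * 5))
  # power: 3-pooled-SD shift at n=22/22 detected in >= 95% of simulations
  hits <- sapply(1:40, function(i) {
    set.seed(600 + i)
    x <- rnorm(22); y <- rnorm(22) + 3
    compare_channel_weights(mk(x), mk(y), channel = 1)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})
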