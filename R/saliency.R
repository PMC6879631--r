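#' Feature stack
#'
#' K aligned feature maps on a common raster, the inputs to the linear
#' saliency readout.  Stored as an `H x W x K` array with a channel-id
#' vector.  Any feature source can be plugged in; the built-in synthetic
#' bank ([make_feature_bank()]) is used throughout the tests, and activation
#' maps of a pretrained convolutional network can be supplied externally in
#' the same container.
#'
#' @param maps `H x W x K` numeric array, all finite.
#' @param channel_ids identifiers, length K (default `1:K`).
#' @param image_id identifier of the aligned image.
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(maps, channel_ids = NULL, image_id = NA_character_) {
  stopifnot(is.array(maps), length(dim(maps)) == 3L, all(is.finite(maps)))
  K <- dim(maps)[3]
  if (is.null(channel_ids)) channel_ids <- seq_len(K)
  stopifnot(length(channel_ids) == K)
  structure(list(maps = maps, channel_ids = channel_ids, image_id = image_id),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<feature_stack> image %s: %d channels on %d x %d raster\n",
              x$image_id, d[3], d[2], d[1]))
  invisible(x)
}

# Bilinear interpolation of a matrix to a target raster (width, height).
bilinear_resize <- function(m, target_wh) {
  th <- target_wh[2]; tw <- target_wh[1]
  sh <- nrow(m); sw <- ncol(m)
  if (th < 1 || tw < 1) stop("degenerate target raster", call. = FALSE)
  # map target pixel centres into source pixel-centre coordinates
  sy <- if (th == 1) (sh - 1) / 2 else (seq_len(th) - 1) * (sh - 1) / (th - 1)
  sx <- if (tw == 1) (sw - 1) / 2 else (seq_len(tw) - 1) * (sw - 1) / (tw - 1)
  y0 <- pmin(floor(sy), sh - 2); y0[y0 < 0] <- 0
  x0 <- pmin(floor(sx), sw - 2); x0[x0 < 0] <- 0
  if (sh == 1) y0 <- rep(0, th)
  if (sw == 1) x0 <- rep(0, tw)
  fy <- sy - y0; fx <- sx - x0
  i0 <- y0 + 1; i1 <- pmin(y0 + 2, sh)
  j0 <- x0 + 1; j1 <- pmin(x0 + 2, sw)
  A <- m[i0, j0, drop = FALSE]; B <- m[i0, j1, drop = FALSE]
  C <- m[i1, j0, drop = FALSE]; D <- m[i1, j1, drop = FALSE]
  wfy <- matrix(fy, th, tw); wfx <- matrix(fx, th, tw, byrow = TRUE)
  (1 - wfy) * ((1 - wfx) * A + wfx * B) + wfy * ((1 - wfx) * C + wfx * D)
}

#' Resize feature maps to a target raster
#'
#' Bilinear interpolation per channel, used to bring raw feature maps (for
#' example coarse convolutional activations) to the resolution of the input
#' image before the linear readout.
#'
#' @param stack a [feature_stack()] (or bare `H x W x K` array).
#' @param target_raster `c(width, height)` of the target grid.
#' @return a [feature_stack()] on the target raster.
#' @export
resize_feature_maps <- function(stack, target_raster) {
  raw <- if (inherits(stack, "feature_stack")) stack$maps else stack
  stopifnot(is.array(raw), length(dim(raw)) == 3L)
  if (any(target_raster < 1)) stop("degenerate target raster", call. = FALSE)
  K <- dim(raw)[3]
  out <- array(0, dim = c(target_raster[2], target_raster[1], K))
  for (k in seq_len(K)) out[, , k] <- bilinear_resize(raw[, , k], target_raster)
  feature_stack(out,
                channel_ids = if (inherits(stack, "feature_stack"))
                  stack$channel_ids else seq_len(K),
                image_id = if (inherits(stack, "feature_stack"))
                  stack$image_id else NA_character_)
}

#' Resample an attention map to the feature raster
#'
#' Bilinear resize followed by re-normalisation, used to align measured
#' attention maps with a feature stack before learning.
#'
#' @param map an [attention_map()].
#' @param target_raster `c(width, height)`.
#' @return an [attention_map()] on the target raster.
#' @export
resample_map <- function(map, target_raster) {
  stopifnot(inherits(map, "attention_map"))
  attention_map(pmax(bilinear_resize(map$grid, target_raster), 0),
                n_subjects = map$n_subjects, method = map$method,
                image_id = map$image_id)
}

#' Weight vector of the linear saliency readout
#'
#' K channel weights learned from (feature stack, attention map) pairs; the
#' per-subject version is a signature of how that subject hierarchically
#' weighted high-level visual features.
#'
#' @param weights numeric length-K, finite.
#' @param learner `"wcorr"` or `"regression"`.
#' @param channel_ids channel identifiers.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights, learner = "wcorr", channel_ids = NULL) {
  stopifnot(is.numeric(weights), all(is.finite(weights)))
  if (is.null(channel_ids)) channel_ids <- seq_along(weights)
  stopifnot(length(channel_ids) == length(weights))
  structure(list(weights = as.numeric(weights), learner = learner,
                 channel_ids = channel_ids),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> %d channels, learner = %s; top channel %s (w = %.3f)\n",
              length(x$weights), x$learner,
              x$channel_ids[which.max(x$weights)], max(x$weights)))
  invisible(x)
}

stack_pixel_matrix <- function(stack) {
  d <- dim(stack$maps)
  matrix(stack$maps, nrow = d[1] * d[2], ncol = d[3])
}

#' Learn readout weights by mean channel-target correlation (wCorr)
#'
#' Fast independent estimate of the K weights: for each channel, the mean
#' over images of the Pearson correlation between the channel's feature map
#' and the measured attention map.  Channels that are constant on an image
#' are skipped for that image (logged as a warning).
#'
#' @param stacks list of [feature_stack()], one per image.
#' @param targets list of [attention_map()] on the feature raster, same
#'   length and order.
#' @return a [weight_vector()] with `learner = "wcorr"`.
#' @export
learn_weights_wcorr <- function(stacks, targets) {
  stopifnot(length(stacks) >= 1L, length(stacks) == length(targets))
  K <- dim(stacks[[1]]$maps)[3]
  acc <- matrix(NA_real_, nrow = length(stacks), ncol = K)
  n_skipped <- 0L
  for (i in seq_along(stacks)) {
    X <- stack_pixel_matrix(stacks[[i]])
    y <- as.vector(targets[[i]]$grid)
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) acc[i, ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d constant channel-image pair(s) skipped", n_skipped))
  }
  weight_vector(colMeans(acc, na.rm = TRUE), learner = "wcorr",
                channel_ids = stacks[[1]]$channel_ids)
}

#' Learn readout weights by lasso-regularised regression
#'
#' Sparse linear regression of pixelwise attention values on the K channel
#' values, with the regularisation strength chosen by 10-fold
#' cross-validation over glmnet's automatic lambda grid.  `lambda = 0`
#' requests the unregularised least-squares limit.  To bound memory and
#' time, pixel rows are deterministically subsampled (fixed stride) when
#' they exceed `max_pixels`.
#'
#' @param stacks,targets as in [learn_weights_wcorr()].
#' @param lambda `"cv"` (default) or a single non-negative number.
#' @param n_folds folds for cross-validation (default 10).
#' @param max_pixels row cap before stride subsampling (default 60000).
#' @return a [weight_vector()] with `learner = "regression"` and attribute
#'   `intercept`.
#' @export
learn_weights_regression <- function(stacks, targets, lambda = "cv",
                                     n_folds = 10, max_pixels = 60000) {
  stopifnot(length(stacks) >= 1L, length(stacks) == length(targets))
  X <- do.call(rbind, lapply(stacks, stack_pixel_matrix))
  y <- unlist(lapply(targets, function(t) as.vector(t$grid)))
  if (nrow(X) > max_pixels) {
    idx <- seq(1L, nrow(X), by = ceiling(nrow(X) / max_pixels))
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  if (all(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate design: all channels constant", call. = FALSE)
  }
  K <- ncol(X)
  if (identical(lambda, 0) || identical(lambda, 0L)) {
    fit <- stats::lm.fit(cbind(1, X), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    w <- weight_vector(co[-1], learner = "regression",
                       channel_ids = stacks[[1]]$channel_ids)
    attr(w, "intercept") <- co[1]
    return(w)
  }
  if (identical(lambda, "cv")) {
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = n_folds)
    lam <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    stopifnot(is.numeric(lambda), lambda > 0)
    lam <- lambda
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda)
  }
  co <- as.numeric(glmnet::coef.glmnet(fit, s = lam))
  w <- weight_vector(co[-1], learner = "regression",
                     channel_ids = stacks[[1]]$channel_ids)
  attr(w, "intercept") <- co[1]
  attr(w, "lambda") <- lam
  w
}

#' Predict a saliency map from a feature stack and weights
#'
#' Pixelwise weighted sum of the K channels, shifted to be non-negative and
#' unity-normalised.  An all-equal output is returned as a flagged constant
#' map rather than an error (check the `constant` field).
#'
#' @param stack a [feature_stack()].
#' @param w a [weight_vector()] with matching K.
#' @return an [attention_map()] with `method = "model"`.
#' @export
predict_saliency <- function(stack, w) {
  stopifnot(inherits(stack, "feature_stack"), inherits(w, "weight_vector"))
  K <- dim(stack$maps)[3]
  if (length(w$weights) != K) stop("channel count mismatch", call. = FALSE)
  d <- dim(stack$maps)
  pred <- matrix(stack_pixel_matrix(stack) %*% w$weights, nrow = d[1])
  # unity normalisation divides by the max; shift first only if negative
  # values occur (possible with negative weights) so the result stays in [0,1]
  if (min(pred) < 0) pred <- pred - min(pred)
  attention_map(pred, method = "model", image_id = stack$image_id)
}

#' Leave-one-out cross-validation of the saliency readout
#'
#' For each image, learn weights on all other images, predict its saliency
#' map, and score the prediction with the Pearson correlation (CC score)
#' against the measured attention map.  A learner failure on a fold yields
#' `NA` for that fold and the run continues.
#'
#' @param stacks,targets as in [learn_weights_wcorr()]; at least 3 images.
#' @param learner `"wcorr"` or `"regression"`.
#' @param ... passed to the learner.
#' @return numeric vector of per-image CC scores (possibly with `NA`s).
#' @export
loo_cross_validate <- function(stacks, targets,
                               learner = c("wcorr", "regression"), ...) {
  learner <- match.arg(learner)
  M <- length(stacks)
  stopifnot(M >= 3L, length(targets) == M)
  fit_fun <- switch(learner, wcorr = learn_weights_wcorr,
                    regression = learn_weights_regression)
  vapply(seq_len(M), function(i) {
    cc <- tryCatch({
      w <- fit_fun(stacks[-i], targets[-i], ...)
      pred <- predict_saliency(stacks[[i]], w)
      if (pred$constant || targets[[i]]$constant) NA_real_ else
        stats::cor(as.vector(pred$grid), as.vector(targets[[i]]$grid))
    }, error = function(e) NA_real_)
    cc
  }, numeric(1))
}

#' Rank channels by learned weight
#'
#' Stable descending sort of the channels by weight; ties are broken by
#' channel id (ascending) for determinism.
#'
#' @param w a [weight_vector()].
#' @return channel ids in descending-weight order.
#' @export
rank_channels <- function(w) {
  stopifnot(inherits(w, "weight_vector"))
  ord <- order(-w$weights, w$channel_ids)
  w$channel_ids[ord]
}

#' Most responsive pixels of a feature channel
#'
#' For each image, the pixels whose activation in the given channel lies in
#' the top `top_fraction` quantile; used to visualise what a channel
#' responds to across an image database.
#'
#' @param stacks list of [feature_stack()].
#' @param channel index of the channel within the stacks.
#' @param top_fraction fraction of pixels to keep, in (0, 1].
#' @return list of logical mask matrices, one per image.
#' @export
most_responsive_pixels <- function(stacks, channel, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  lapply(stacks, function(s) {
    m <- s$maps[, , channel]
    thr <- stats::quantile(m, probs = 1 - top_fraction, names = FALSE,
                           type = 1)
    mask <- m >= thr
    if (top_fraction == 1) mask[] <- TRUE
    mask
  })
}

#' Chance probability of a top-channel match
#'
#' If two independently learned feature hierarchies place the same
#' prespecified channel first, the null (independent random ranking)
#' probability of that event is `1/K`.  With the standard K = 256 channel
#' bank this is 0.00390625 (< 0.004).
#'
#' @param K number of channels (default 256).
#' @return `1 / K`.
#' @export
top_channel_match_pvalue <- function(K = 256) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1)
  1 / K
}

#' Compare per-subject channel weights between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-subject weights of one
#' channel, with Bonferroni correction over the number of channels tested.
#'
#' @param groupA,groupB lists of per-subject [weight_vector()] objects
#'   (>= 3 subjects each).
#' @param channel channel index to test.
#' @param n_tested number of channels in the testing family (Bonferroni
#'   multiplier; default 1).
#' @return list with `p_value` (corrected, capped at 1), `p_uncorrected`,
#'   `statistic`.
#' @export
compare_channel_weights <- function(groupA, groupB, channel, n_tested = 1) {
  stopifnot(length(groupA) >= 3L, length(groupB) >= 3L, n_tested >= 1)
  a <- vapply(groupA, function(w) w$weights[channel], numeric(1))
  b <- vapply(groupB, function(w) w$weights[channel], numeric(1))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p_value = min(1, ht$p.value * n_tested),
       p_uncorrected = ht$p.value,
       statistic = unname(ht$statistic))
}
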