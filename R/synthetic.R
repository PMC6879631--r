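#' Population profile for simulated explorers
#'
#' Describes how a simulated population allocates attention: per-channel
#' preference weights over the scene's semantic channels (eyes, face,
#' object, background), a lateral bias (fraction of exploration mass
#' directed right of the display midline), and a positional jitter sd.
#'
#' Three presets emulate the populations studied with this method:
#' * [profile_neurotypical()] — strong attraction to the eye region, then
#'   face, then objects (the canonical neurotypical feature hierarchy).
#' * [profile_eyes_avoidant()] — the eye-region preference collapses while
#'   whole-face exploration is preserved, the atypical pattern reported in
#'   rehabilitated high-functioning autistic adults.
#' * [profile_left_neglect()] — neurotypical preferences but 85% of
#'   exploration mass directed right of the midline, emulating left
#'   hemispatial neglect after right-parietal damage.
#'
#' @param preferences named numeric vector of channel-role weights.
#' @param lateral_bias fraction in `[0, 1]` of exploration mass right of the
#'   display midline, enforced exactly by the simulators (each sample's side
#'   is preserved through positional jitter).  `NA` (the default for the
#'   non-neglect presets) leaves the scene's natural lateral asymmetry
#'   untouched.
#' @param jitter_px sd of Gaussian positional jitter, in scene pixels
#'   (defaults assume the 256-px-wide default scene; scale with the raster).
#' @param n_subjects default cohort size for [make_population()].
#' @param name label.
#' @return An object of class `population_profile`.
#' @export
population_profile <- function(preferences = c(eyes = 1, face = 0.6,
                                               object = 0.4,
                                               background = 0.05),
                               lateral_bias = NA, jitter_px = 8,
                               n_subjects = 11, name = "custom") {
  stopifnot(all(is.finite(preferences)), !is.null(names(preferences)),
            is.na(lateral_bias) ||
              (lateral_bias >= 0 && lateral_bias <= 1),
            jitter_px >= 0, n_subjects >= 0)
  structure(list(preferences = preferences, lateral_bias = lateral_bias,
                 jitter_px = jitter_px, n_subjects = n_subjects,
                 name = name),
            class = "population_profile")
}

#' @rdname population_profile
#' @export
profile_neurotypical <- function(n_subjects = 11, jitter_px = 8) {
  population_profile(n_subjects = n_subjects, jitter_px = jitter_px,
                     name = "neurotypical")
}

#' @rdname population_profile
#' @export
profile_eyes_avoidant <- function(n_subjects = 22, jitter_px = 8) {
  population_profile(preferences = c(eyes = 0.1, face = 0.9, object = 0.5,
                                     background = 0.05),
                     n_subjects = n_subjects, jitter_px = jitter_px,
                     name = "eyes_avoidant")
}

#' @rdname population_profile
#' @param lateral_bias see above; 0.85 emulates the severe right-bias seen
#'   in left-neglect sessions.
#' @export
profile_left_neglect <- function(lateral_bias = 0.85, n_subjects = 5,
                                 jitter_px = 8) {
  population_profile(lateral_bias = lateral_bias, n_subjects = n_subjects,
                     jitter_px = jitter_px, name = "left_neglect")
}

#' Explorer configuration
#'
#' Acquisition parameters for the simulated explorers.  Digit defaults
#' reproduce the tablet task's stated arithmetic: finger speed 1000 px/s
#' and a 4000 px path threshold, i.e. an exploration quantity equivalent to
#' a 4-s eye-tracking trial.  `dwell_s` adds stationary samples at each
#' waypoint ("slowing around regions of interest"); it defaults to 0 so the
#' trajectory duration equals `path / speed` exactly, and is switched on by
#' the population generator for realism.
#'
#' @param mode `"eye"` or `"digit"`.
#' @param sampling_rate_hz sample rate for digit trajectories (default 60).
#' @param trial_duration_s eye-mode trial length in seconds (default 4).
#' @param speed_px_s digit-mode finger speed (default 1000).
#' @param path_threshold_px digit-mode stopping threshold (default 4000).
#' @param dwell_s stationary dwell at each digit waypoint, seconds.
#' @param median_fix_s,sdlog_fix log-normal fixation-duration parameters
#'   (median 0.25 s).
#' @return An object of class `explorer_config`.
#' @export
explorer_config <- function(mode = c("eye", "digit"), sampling_rate_hz = 60,
                            trial_duration_s = 4, speed_px_s = 1000,
                            path_threshold_px = 4000, dwell_s = 0,
                            median_fix_s = 0.25, sdlog_fix = 0.5) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  stop_if_not_scalar_pos(trial_duration_s, "trial_duration_s")
  stop_if_not_scalar_pos(speed_px_s, "speed_px_s")
  stop_if_not_scalar_pos(path_threshold_px, "path_threshold_px")
  stopifnot(dwell_s >= 0)
  structure(list(mode = mode, sampling_rate_hz = sampling_rate_hz,
                 trial_duration_s = trial_duration_s,
                 speed_px_s = speed_px_s,
                 path_threshold_px = path_threshold_px, dwell_s = dwell_s,
                 median_fix_s = median_fix_s, sdlog_fix = sdlog_fix),
            class = "explorer_config")
}

gaussian_blob <- function(raster, cx, cy, sigma) {
  w <- raster[1]; h <- raster[2]
  exp(-(outer((seq_len(h) - 1 - cy)^2, (seq_len(w) - 1 - cx)^2, `+`)) /
        (2 * sigma^2))
}

#' Synthetic scene with ground-truth saliency
#'
#' Renders a cartoon scene of Gaussian blobs playing semantic roles (a face
#' containing an eye region, a non-social object, a broad background
#' texture), the per-role channel-truth maps, and the normalised mixture
#' saliency that drives the simulated explorers.  Blob positions are
#' jittered per seed within safe margins; the weighted channel sum equals
#' the ground-truth saliency by construction.
#'
#' @param raster `c(width, height)` (default `c(256, 205)`, the 1280 x 1024
#'   analysis space scaled by 1/5).
#' @param blobs optional data.frame with columns `role`, `x`, `y`, `sigma`
#'   overriding the default layout (one row per blob; the two eye blobs
#'   share the role `"eyes"`).
#' @param mixture named channel mixture weights of the generating saliency.
#' @param seed RNG seed (position jitter and image texture).
#' @return An object of class `scene`: fields `image`, `saliency` (matrix,
#'   max 1), `channels` (H x W x R array), `roles`, `mixture`, `raster`,
#'   `image_id`, `blobs`.
#' @export
make_scene <- function(raster = c(256, 205), blobs = NULL,
                       mixture = c(eyes = 1, face = 0.6, object = 0.5,
                                   background = 0.15),
                       seed = 1) {
  w <- raster[1]; h <- raster[2]
  blobs <- if (is.null(blobs)) {
    with_seed(seed, {
      fx <- w * stats::runif(1, 0.38, 0.62)
      fy <- h * stats::runif(1, 0.33, 0.5)
      ox <- w * stats::runif(1, 0.6, 0.85)
      oy <- h * stats::runif(1, 0.62, 0.85)
      data.frame(
        role = c("eyes", "eyes", "face", "object", "background"),
        x = c(fx - 0.07 * w, fx + 0.07 * w, fx, ox, w / 2),
        y = c(fy - 0.05 * h, fy - 0.05 * h, fy, oy, h / 2),
        sigma = c(0.030 * w, 0.030 * w, 0.16 * w, 0.07 * w, 0.6 * w),
        stringsAsFactors = FALSE)
    })
  } else {
    stopifnot(all(c("role", "x", "y", "sigma") %in% names(blobs)))
    blobs
  }
  if (nrow(blobs) < 1L) stop("at least one blob is required", call. = FALSE)
  roles <- unique(blobs$role)
  channels <- array(0, dim = c(h, w, length(roles)),
                    dimnames = list(NULL, NULL, roles))
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    channels[, , b$role] <- channels[, , b$role] +
      gaussian_blob(raster, b$x, b$y, b$sigma)
  }
  for (r in roles) {
    mx <- max(channels[, , r])
    if (mx > 0) channels[, , r] <- channels[, , r] / mx
  }
  mw <- mixture[roles]
  mw[is.na(mw)] <- 0
  sal <- matrix(0, h, w)
  for (r in roles) sal <- sal + mw[r] * channels[, , r]
  sal_max <- max(sal)
  if (sal_max > 0) sal <- sal / sal_max
  image <- with_seed(child_seed(seed, 7L), {
    tex <- blur_matrix(matrix(stats::rnorm(h * w, 0, 0.05), h, w), w / 40)
    img <- 0.2 + 0.7 * sal + tex
    pmin(pmax(img, 0), 1)
  })
  structure(list(image = image, saliency = sal, channels = channels,
                 roles = roles, mixture = mw, mixture_scale = sal_max,
                 raster = raster, image_id = sprintf("scene_%03d", seed),
                 blobs = blobs),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s: %d x %d px, roles: %s\n", x$image_id,
              x$raster[1], x$raster[2], paste(x$roles, collapse = ", ")))
  invisible(x)
}

#' Personal exploration density of a profile on a scene
#'
#' The profile-reweighted mixture of the scene's channel-truth maps,
#' laterally reweighted so that exactly `lateral_bias` of the probability
#' mass lies right of the raster midline, returned as a probability matrix
#' (sums to 1).  Each channel is first normalised to unit total mass, so a
#' preference vector reads as relative *quantities* of exploration per
#' channel: with the neurotypical preset (eyes 1, face 0.6, object 0.4,
#' background 0.05) about half of all exploration lands on the eye region,
#' the canonical top-attractor bias, regardless of how large each blob is.
#'
#' @param scene a [make_scene()] object.
#' @param profile a [population_profile()].
#' @return H x W probability matrix.
#' @export
subject_saliency <- function(scene, profile) {
  stopifnot(inherits(scene, "scene"), inherits(profile, "population_profile"))
  pref <- profile$preferences[scene$roles]
  pref[is.na(pref)] <- 0
  p <- matrix(0, nrow(scene$saliency), ncol(scene$saliency))
  for (r in scene$roles) {
    ch <- scene$channels[, , r]
    mass <- sum(ch)
    if (mass > 0) p <- p + pref[r] * ch / mass
  }
  if (max(p) <= 0) stop("profile puts zero mass on every channel", call. = FALSE)
  w <- scene$raster[1]
  b <- profile$lateral_bias
  if (!is.na(b)) {
    right <- (seq_len(w) - 1) > w / 2   # strict: a column on the midline is left
    mr <- sum(p[, right]); ml <- sum(p[, !right])
    if (mr > 0 && ml > 0) {
      p[, right] <- p[, right] * (b / mr)
      p[, !right] <- p[, !right] * ((1 - b) / ml)
    }
  }
  p / sum(p)
}

# Draw n exploration points from a pixel probability matrix with Gaussian
# positional jitter, clamped to the raster.  When `enforce_mid` is given,
# each point's side of the midline (assigned before jitter) is preserved by
# clamping at the midline, so a profile's lateral-bias dial stays exact
# under jitter.  Caller manages the RNG state.
draw_points <- function(prob, n, jitter_px, enforce_mid = NULL) {
  h <- nrow(prob); w <- ncol(prob)
  idx <- sample.int(h * w, n, replace = TRUE, prob = as.vector(prob))
  y <- (idx - 1) %% h
  x <- (idx - 1) %/% h
  right <- if (is.null(enforce_mid)) NULL else x > enforce_mid
  if (jitter_px > 0) {
    x <- x + stats::rnorm(n, 0, jitter_px)
    y <- y + stats::rnorm(n, 0, jitter_px)
  }
  if (!is.null(right)) {
    x[right] <- pmax(x[right], enforce_mid + 1e-9)
    x[!right] <- pmin(x[!right], enforce_mid - 1e-9)
  }
  data.frame(x = pmin(pmax(x, 0), w - 1), y = pmin(pmax(y, 0), h - 1))
}

profile_mid <- function(scene, profile) {
  if (is.na(profile$lateral_bias)) NULL else scene$raster[1] / 2
}

#' Simulate one eye-tracking subject
#'
#' Draws fixation locations from the profile's personal exploration density
#' with positional jitter; durations are log-normal (median
#' `cfg$median_fix_s`); fixations accumulate until the trial duration is
#' reached.  Deterministic under `seed`.
#'
#' @param scene a [make_scene()] scene.
#' @param profile a [population_profile()].
#' @param cfg an [explorer_config()] with `mode = "eye"`.
#' @param seed RNG seed.
#' @param subject_id identifier.
#' @return a [fixation_set()].
#' @export
simulate_eye_subject <- function(scene, profile, cfg = explorer_config("eye"),
                                 seed = 1, subject_id = "sim") {
  stopifnot(inherits(cfg, "explorer_config"))
  prob <- subject_saliency(scene, profile)
  with_seed(seed, {
    durs <- numeric(0)
    while (sum(durs) < cfg$trial_duration_s) {
      durs <- c(durs, stats::rlnorm(8, log(cfg$median_fix_s), cfg$sdlog_fix))
    }
    n <- which(cumsum(durs) >= cfg$trial_duration_s)[1]
    durs <- durs[seq_len(n)]
    pts <- draw_points(prob, n, profile$jitter_px, profile_mid(scene, profile))
    onsets <- c(0, cumsum(durs))[seq_len(n)]
    fixation_set(pts$x, pts$y, onsets, durs * 1000,
                 subject_id = subject_id, image_id = scene$image_id,
                 method = "eye")
  })
}

#' Simulate one digit-tracking subject
#'
#' Waypoints are sampled from the personal exploration density like
#' fixations; the finger moves between them at constant speed, optionally
#' pausing `cfg$dwell_s` seconds at each waypoint, sampled at
#' `cfg$sampling_rate_hz`; the trajectory is truncated by
#' [truncate_at_path_threshold()] at `cfg$path_threshold_px`.  With the
#' default `dwell_s = 0`, the returned duration equals
#' `path_threshold_px / speed_px_s` up to one sampling interval.
#'
#' @inheritParams simulate_eye_subject
#' @param cfg an [explorer_config()] with `mode = "digit"`.
#' @return a [trajectory()] (truncated at the path threshold).
#' @export
simulate_digit_subject <- function(scene, profile,
                                   cfg = explorer_config("digit"),
                                   seed = 1, subject_id = "sim") {
  stopifnot(inherits(cfg, "explorer_config"))
  prob <- subject_saliency(scene, profile)
  with_seed(seed, {
    wx <- numeric(0); wy <- numeric(0)
    path <- 0
    repeat {
      pts <- draw_points(prob, 8L, profile$jitter_px,
                         profile_mid(scene, profile))
      wx <- c(wx, pts$x); wy <- c(wy, pts$y)
      path <- sum(sqrt(diff(wx)^2 + diff(wy)^2))
      if (path >= cfg$path_threshold_px * 1.05 + 1) break
    }
    # knot times: arrival and departure (after dwell) at each waypoint
    m <- length(wx)
    seg <- sqrt(diff(wx)^2 + diff(wy)^2)
    kt <- numeric(0); kx <- numeric(0); ky <- numeric(0)
    t <- 0
    for (i in seq_len(m)) {
      kt <- c(kt, t); kx <- c(kx, wx[i]); ky <- c(ky, wy[i])
      if (cfg$dwell_s > 0) {
        t <- t + cfg$dwell_s
        kt <- c(kt, t); kx <- c(kx, wx[i]); ky <- c(ky, wy[i])
      }
      if (i < m) t <- t + seg[i] / cfg$speed_px_s
    }
    ts <- seq(0, max(kt), by = 1 / cfg$sampling_rate_hz)
    xs <- stats::approx(kt, kx, xout = ts, ties = "ordered")$y
    ys <- stats::approx(kt, ky, xout = ts, ties = "ordered")$y
    traj <- trajectory(ts, xs, ys, subject_id = subject_id,
                       image_id = scene$image_id)
    truncate_at_path_threshold(traj, cfg$path_threshold_px)
  })
}

#' Synthetic feature bank for a scene
#'
#' A K-channel feature stack on the scene raster: the scene's semantic
#' channel-truth maps first (the "high-level" channels), then smooth random
#' fields (Gaussian-filtered white noise, scaled to `[0, 1]`) standing in
#' for the remaining channels of a convolutional feature extractor.
#' Deterministic under `seed`.
#'
#' @param scene a [make_scene()] scene.
#' @param K total number of channels (default 16; >= number of roles).
#' @param seed RNG seed for the noise channels.
#' @param include_roles prepend the semantic channels (default TRUE).
#' @return a [feature_stack()].
#' @export
make_feature_bank <- function(scene, K = 16, seed = 1, include_roles = TRUE) {
  stopifnot(inherits(scene, "scene"), K >= 1)
  h <- nrow(scene$saliency); w <- ncol(scene$saliency)
  R <- if (include_roles) length(scene$roles) else 0L
  stopifnot(K >= R)
  maps <- array(0, dim = c(h, w, K))
  if (R > 0L) maps[, , seq_len(R)] <- scene$channels
  if (K > R) {
    noise <- with_seed(seed, {
      lapply(seq_len(K - R), function(k) {
        f <- blur_matrix(matrix(stats::rnorm(h * w), h, w), w / 16)
        f <- f - min(f)
        f / max(f)
      })
    })
    for (k in seq_len(K - R)) maps[, , R + k] <- noise[[k]]
  }
  feature_stack(maps, image_id = scene$image_id)
}

#' Synthetic weight-recovery dataset
#'
#' Builds `n_images` scenes with K-channel feature banks and targets that
#' are noisy linear mixtures of the channels under known generating
#' weights: `target = normalise(mix + noise)` with a smooth noise field of
#' sd `sd(mix) / snr`.  Used by the parameter-recovery tests of the linear
#' readout.
#'
#' @param n_images number of images.
#' @param K channels per bank.
#' @param snr signal-to-noise ratio of the targets (default 5).
#' @param weights generating weights (length K); default: evenly spaced
#'   from 1 down to -0.5, shuffled deterministically under `seed`.
#' @param raster scene raster (default `c(64, 64)` for speed).
#' @param seed RNG seed.
#' @param include_roles prepend the scene's semantic channels to each bank
#'   (default TRUE).  Use FALSE for clean parameter-recovery tests: the
#'   semantic channels overlap spatially (the eye region sits inside the
#'   face), which blurs exact rank recovery.
#' @return list with `stacks`, `targets`, `weights` (the generating truth),
#'   `scenes`.
#' @export
make_recovery_dataset <- function(n_images = 30, K = 16, snr = 5,
                                  weights = NULL, raster = c(64, 64),
                                  seed = 1, include_roles = TRUE) {
  stopifnot(n_images >= 1L, K >= 2L, snr > 0)
  if (is.null(weights)) {
    weights <- with_seed(child_seed(seed, 1L),
                         sample(seq(1, -0.5, length.out = K)))
  }
  stopifnot(length(weights) == K)
  scenes <- lapply(seq_len(n_images),
                   function(i) make_scene(raster = raster,
                                          seed = child_seed(seed, 2L, i)))
  stacks <- lapply(seq_along(scenes), function(i) {
    make_feature_bank(scenes[[i]], K = K, seed = child_seed(seed, 3L, i),
                      include_roles = include_roles)
  })
  targets <- lapply(seq_along(stacks), function(i) {
    X <- stack_pixel_matrix(stacks[[i]])
    mix <- matrix(X %*% weights, nrow = raster[2])
    noise <- with_seed(child_seed(seed, 4L, i), {
      f <- blur_matrix(matrix(stats::rnorm(length(mix)), nrow(mix)),
                       raster[1] / 16)
      f / stats::sd(f) * stats::sd(mix) / snr
    })
    g <- mix + noise
    g <- g - min(g)
    attention_map(g, method = "model",
                  image_id = stacks[[i]]$image_id)
  })
  list(stacks = stacks, targets = targets, weights = weights,
       scenes = scenes)
}

#' Simulate a full population dataset
#'
#' Per profile and per scene, simulates `n_subjects` exploration records in
#' the requested mode, with a manifest of group labels.  Deterministic
#' under `seed` (each record gets a child seed derived from group, subject
#' and scene indices).
#'
#' @param profiles named list of [population_profile()] objects (names are
#'   the group labels).
#' @param scenes list of [make_scene()] scenes.
#' @param cfg an [explorer_config()] (its `mode` decides the record type).
#' @param seed RNG seed.
#' @return list with `records` (flat list of [fixation_set()] /
#'   [trajectory()]) and `manifest` (data.frame: record, group, subject_id,
#'   image_id, mode).
#' @export
make_population <- function(profiles, scenes, cfg, seed = 1) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)),
            inherits(cfg, "explorer_config"))
  records <- list()
  rows <- list()
  k <- 0L
  for (g in seq_along(profiles)) {
    prof <- profiles[[g]]
    grp <- names(profiles)[g]
    for (s in seq_len(prof$n_subjects)) {
      sid <- sprintf("%s_%02d", grp, s)
      for (i in seq_along(scenes)) {
        k <- k + 1L
        sd <- child_seed(seed, g, s, i)
        rec <- if (cfg$mode == "eye") {
          simulate_eye_subject(scenes[[i]], prof, cfg, seed = sd,
                               subject_id = sid)
        } else {
          simulate_digit_subject(scenes[[i]], prof, cfg, seed = sd,
                                 subject_id = sid)
        }
        records[[k]] <- rec
        rows[[k]] <- data.frame(record = k, group = grp, subject_id = sid,
                                image_id = scenes[[i]]$image_id,
                                mode = cfg$mode, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows) == 0L) {
    data.frame(record = integer(0), group = character(0),
               subject_id = character(0), image_id = character(0),
               mode = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  list(records = records, manifest = manifest)
}
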