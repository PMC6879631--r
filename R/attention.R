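#' Fixation set
#'
#' Discrete fixations with 0-based pixel coordinates, onsets in seconds and
#' durations in milliseconds, tagged with acquisition method (`"eye"` or
#' `"digit"`).
#'
#' @param x_px,y_px fixation centroids, pixels.
#' @param onset_s onsets in seconds.
#' @param duration_ms durations in milliseconds.
#' @param subject_id,image_id identifiers.
#' @param method `"eye"` or `"digit"`.
#' @return An object of class `fixation_set`.
#' @export
fixation_set <- function(x_px, y_px, onset_s, duration_ms,
                         subject_id = NA_character_, image_id = NA_character_,
                         method = c("eye", "digit")) {
  method <- match.arg(method)
  n <- length(x_px)
  stopifnot(length(y_px) == n, length(onset_s) == n, length(duration_ms) == n)
  if (n > 0L && any(duration_ms < 0)) stop("negative duration", call. = FALSE)
  structure(
    list(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
         onset_s = as.numeric(onset_s), duration_ms = as.numeric(duration_ms),
         subject_id = subject_id, image_id = image_id, method = method),
    class = "fixation_set")
}

#' @export
print.fixation_set <- function(x, ...) {
  cat(sprintf("<fixation_set> subject %s, image %s (%s): %d fixations, total %.0f ms\n",
              x$subject_id, x$image_id, x$method, length(x$x_px),
              sum(x$duration_ms)))
  invisible(x)
}

#' Detect fixations in a regularly sampled gaze stream
#'
#' Dispersion-style grouping: maximal runs of consecutive samples whose
#' distance to the running centroid stays within `radius_px` become fixation
#' candidates; a candidate is emitted when its temporal span reaches
#' `min_duration_ms`.  Runs are split at sampling gaps larger than
#' `min_duration_ms`.  Fixations whose centroid falls outside the raster
#' bounds (when `bounds` is given) are dropped.
#'
#' The exact vendor algorithm behind commercial "fixation radius" filters is
#' unpublished; this dispersion rule is a documented stand-in with the same
#' two parameters (defaults 50 px / 50 ms).
#'
#' @param traj a [trajectory()].
#' @param radius_px dispersion radius in pixels.
#' @param min_duration_ms minimum fixation duration, milliseconds.
#' @param bounds optional `c(width, height)` of the valid raster; fixations
#'   outside are discarded.
#' @return a [fixation_set()] with `method = "eye"`.
#' @export
detect_fixations <- function(traj, radius_px = 50, min_duration_ms = 50,
                             bounds = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  stop_if_not_scalar_pos(radius_px, "radius_px")
  stop_if_not_scalar_pos(min_duration_ms, "min_duration_ms")
  n <- length(traj$t_s)
  fx <- fy <- fo <- fd <- numeric(0)
  if (n > 0L) {
    gap_s <- min_duration_ms / 1000
    start <- 1L
    cx <- traj$x_px[1]; cy <- traj$y_px[1]; cnt <- 1L
    emit <- function(i_start, i_end, cx, cy) {
      dur <- (traj$t_s[i_end] - traj$t_s[i_start]) * 1000
      if (dur >= min_duration_ms) {
        fx <<- c(fx, cx); fy <<- c(fy, cy)
        fo <<- c(fo, traj$t_s[i_start]); fd <<- c(fd, dur)
      }
    }
    for (i in seq_len(n)[-1]) {
      gap <- traj$t_s[i] - traj$t_s[i - 1L]
      d <- sqrt((traj$x_px[i] - cx)^2 + (traj$y_px[i] - cy)^2)
      if (gap > gap_s || d > radius_px) {
        emit(start, i - 1L, cx, cy)
        start <- i
        cx <- traj$x_px[i]; cy <- traj$y_px[i]; cnt <- 1L
      } else {
        cnt <- cnt + 1L
        cx <- cx + (traj$x_px[i] - cx) / cnt
        cy <- cy + (traj$y_px[i] - cy) / cnt
      }
    }
    emit(start, n, cx, cy)
  }
  if (!is.null(bounds) && length(fx) > 0L) {
    keep <- fx >= 0 & fx <= bounds[1] - 1 & fy >= 0 & fy <= bounds[2] - 1
    fx <- fx[keep]; fy <- fy[keep]; fo <- fo[keep]; fd <- fd[keep]
  }
  fixation_set(fx, fy, fo, fd, subject_id = traj$subject_id,
               image_id = traj$image_id, method = "eye")
}

#' Attention map
#'
#' A unity-normalised 2-d exploration density on an analysis raster: all
#' values lie in `[0, 1]` and the maximum equals 1 whenever any exploration
#' mass exists.  Stored as a matrix with `grid[row, col]` indexed by
#' `row = y + 1`, `col = x + 1` (0-based pixel coordinates, origin
#' top-left).
#'
#' @param grid numeric matrix of non-negative densities (normalised here).
#' @param n_subjects number of subjects the map aggregates.
#' @param method `"eye"`, `"digit"` or `"model"`.
#' @param image_id identifier.
#' @return An object of class `attention_map`.
#' @export
attention_map <- function(grid, n_subjects = 1L, method = "eye",
                          image_id = NA_character_) {
  stopifnot(is.matrix(grid), all(is.finite(grid)))
  if (any(grid < 0)) stop("density grid must be non-negative", call. = FALSE)
  mx <- max(grid)
  constant <- mx == min(grid)
  if (mx > 0) grid <- grid / mx
  structure(
    list(grid = grid, n_subjects = n_subjects, method = method,
         image_id = image_id, constant = constant),
    class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map> image %s (%s, n=%d): %d x %d raster%s\n",
              x$image_id, x$method, x$n_subjects,
              ncol(x$grid), nrow(x$grid),
              if (x$constant) " [constant]" else ""))
  invisible(x)
}

#' Kernel-density attention map
#'
#' Gaussian-kernel density of exploration points, weighted (by fixation
#' duration for eye data; all-ones for digit samples), evaluated on the
#' analysis raster and unity-normalised:
#' `density(p) = sum_i w_i * exp(-||p - x_i||^2 / (2 h^2))`, then divided by
#' its maximum.  The kernel is truncated at the raster edges without
#' per-point renormalisation; unity normalisation absorbs the overall scale.
#'
#' Evaluation uses the separable form of the Gaussian (an outer-product
#' accumulation), which is algebraically identical to the per-pixel sum.
#'
#' @param x_px,y_px point coordinates (0-based pixels).
#' @param weights non-negative weights, same length (default all ones).
#' @param bandwidth_px Gaussian kernel sigma `h` in pixels (default 30).
#' @param raster `c(width, height)` of the analysis grid.
#' @param method,image_id,n_subjects metadata stored on the result.
#' @return an [attention_map()].
#' @export
kde_attention_map <- function(x_px, y_px, weights = NULL, bandwidth_px = 30,
                              raster = c(1280, 1024), method = "eye",
                              image_id = NA_character_, n_subjects = 1L) {
  n <- length(x_px)
  if (n == 0L) stop("no points: cannot estimate a density", call. = FALSE)
  stopifnot(length(y_px) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) == 0) stop("total weight is zero", call. = FALSE)
  stop_if_not_scalar_pos(bandwidth_px, "bandwidth_px")
  w <- raster[1]; h <- raster[2]
  gx <- seq_len(w) - 1
  gy <- seq_len(h) - 1
  # Gy[row, i] * Gx[i, col] accumulated over points i == brute-force sum
  Gy <- exp(-outer(gy, y_px, `-`)^2 / (2 * bandwidth_px^2))
  Gx <- exp(-outer(x_px, gx, `-`)^2 / (2 * bandwidth_px^2))
  dens <- Gy %*% (weights * Gx)
  attention_map(dens, n_subjects = n_subjects, method = method,
                image_id = image_id)
}

#' Attention map from a fixation set or trajectory
#'
#' Convenience wrappers applying the field conventions: eye fixations enter
#' the KDE weighted by their duration; digit-tracking trajectory samples
#' enter unweighted (each regularly sampled aperture centre counts once, so
#' dwell time is encoded by sample count).
#'
#' @param x a [fixation_set()] or [trajectory()].
#' @param bandwidth_px KDE bandwidth in pixels.
#' @param raster analysis raster `c(width, height)`.
#' @return an [attention_map()].
#' @export
map_from_fixations <- function(x, bandwidth_px = 30, raster = c(1280, 1024)) {
  stopifnot(inherits(x, "fixation_set"))
  kde_attention_map(x$x_px, x$y_px, weights = x$duration_ms,
                    bandwidth_px = bandwidth_px, raster = raster,
                    method = x$method, image_id = x$image_id)
}

#' @rdname map_from_fixations
#' @export
map_from_trajectory <- function(x, bandwidth_px = 30, raster = c(1280, 1024)) {
  stopifnot(inherits(x, "trajectory"))
  keep <- !x$off_screen
  kde_attention_map(x$x_px[keep], x$y_px[keep], weights = NULL,
                    bandwidth_px = bandwidth_px, raster = raster,
                    method = "digit", image_id = x$image_id)
}

#' Group attention map
#'
#' Pixelwise mean of per-subject unity-normalised maps, re-normalised to a
#' maximum of 1.
#'
#' @param maps list of [attention_map()] objects on a common raster.
#' @return an [attention_map()] with `n_subjects` equal to the total count.
#' @export
group_map <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "attention_map")))
  d <- dim(maps[[1]]$grid)
  for (m in maps) {
    if (!identical(dim(m$grid), d)) stop("raster mismatch", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "grid")) / length(maps)
  attention_map(acc,
                n_subjects = sum(vapply(maps, `[[`, numeric(1), "n_subjects")),
                method = maps[[1]]$method, image_id = maps[[1]]$image_id)
}

#' Pearson correlation between two attention maps
#'
#' Computed over all raster pixels of the flattened grids (no masking).
#' Undefined for constant maps.
#'
#' @param a,b [attention_map()] objects on the same raster.
#' @return Pearson r in `[-1, 1]`.
#' @export
map_correlation <- function(a, b) {
  stopifnot(inherits(a, "attention_map"), inherits(b, "attention_map"))
  if (!identical(dim(a$grid), dim(b$grid))) stop("raster mismatch", call. = FALSE)
  if (a$constant || b$constant) {
    stop("correlation undefined for a constant map", call. = FALSE)
  }
  stats::cor(as.vector(a$grid), as.vector(b$grid))
}
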