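#' Display geometry specification
#'
#' Describes the physical and pixel geometry of a display together with the
#' viewing distance.  Every pixel/degree conversion in the package flows
#' through a `display_spec`, so degree-valued parameters stay consistent with
#' the hardware they were calibrated on.
#'
#' Two canonical setups are provided as constructors: [tablet_display()]
#' (a 2736 x 1824 px, 26 cm x 17.3 cm, 267 PPI touch tablet viewed at 32 cm)
#' and [eyetracker_display()] (a 1280 x 1024 px, 33.8 cm x 27.4 cm monitor
#' viewed at 50 cm).
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_cm,height_cm physical size in centimetres.
#' @param viewing_distance_cm eye-to-screen distance in centimetres.
#' @param pixels_per_inch optional; derived from `width_px / width_cm` when
#'   missing.  Must agree with the derived value within 1%.
#'
#' @return An object of class `display_spec`.
#' @examples
#' d <- tablet_display()
#' px_to_degrees(110, d) # ~1.9 degrees, the foveal aperture sigma
#' @export
display_spec <- function(width_px, height_px, width_cm, height_cm,
                         viewing_distance_cm, pixels_per_inch = NULL) {
  for (nm in c("width_px", "height_px", "width_cm", "height_cm",
               "viewing_distance_cm")) {
    stop_if_not_scalar_pos(get(nm), nm)
  }
  derived_ppi <- width_px / (width_cm / 2.54)
  if (is.null(pixels_per_inch)) {
    pixels_per_inch <- derived_ppi
  } else {
    stop_if_not_scalar_pos(pixels_per_inch, "pixels_per_inch")
    if (abs(pixels_per_inch - derived_ppi) / derived_ppi > 0.01) {
      stop("`pixels_per_inch` inconsistent with width_px/width_cm (>1% off)",
           call. = FALSE)
    }
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         viewing_distance_cm = viewing_distance_cm,
         pixels_per_inch = pixels_per_inch),
    class = "display_spec")
}

#' @rdname display_spec
#' @export
tablet_display <- function() {
  display_spec(width_px = 2736, height_px = 1824,
               width_cm = 26, height_cm = 17.3,
               viewing_distance_cm = 32, pixels_per_inch = 267)
}

#' @rdname display_spec
#' @export
eyetracker_display <- function() {
  display_spec(width_px = 1280, height_px = 1024,
               width_cm = 33.8, height_cm = 27.4,
               viewing_distance_cm = 50)
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf("<display_spec> %d x %d px, %.1f x %.1f cm, viewed at %.0f cm (%.0f PPI)\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$viewing_distance_cm, x$pixels_per_inch))
  cat(sprintf("  field of view: %.1f x %.1f degrees\n",
              cm_to_degrees(x$width_cm, x), cm_to_degrees(x$height_cm, x)))
  invisible(x)
}

#' Foveated-rendering configuration
#'
#' Parameters of the gaze-contingent rendering: the Gaussian blur applied to
#' simulate peripheral acuity loss, the Gaussian aperture window simulating
#' foveal vision, the upward shift of the window from the finger contact
#' point (so the fingertip does not mask the unblurred area), and the
#' cumulative path-length threshold that ends a trial.
#'
#' Defaults (40 / 110 / 80 / 4000 px) correspond, on the tablet geometry, to
#' about 0.7 / 1.9 / 1.4 / 68 degrees of visual angle.
#'
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param aperture_sigma_px Gaussian aperture sigma in pixels.
#' @param vertical_offset_px upward shift of the aperture centre, in pixels.
#' @param path_threshold_px cumulative track-path length ending a trial.
#' @return An object of class `render_config`.
#' @export
render_config <- function(blur_sigma_px = 40, aperture_sigma_px = 110,
                          vertical_offset_px = 80, path_threshold_px = 4000) {
  stop_if_not_scalar_pos(blur_sigma_px, "blur_sigma_px")
  stop_if_not_scalar_pos(aperture_sigma_px, "aperture_sigma_px")
  stop_if_not_scalar_pos(vertical_offset_px, "vertical_offset_px")
  stop_if_not_scalar_pos(path_threshold_px, "path_threshold_px")
  structure(
    list(blur_sigma_px = blur_sigma_px, aperture_sigma_px = aperture_sigma_px,
         vertical_offset_px = vertical_offset_px,
         path_threshold_px = path_threshold_px),
    class = "render_config")
}

#' Convert pixels to degrees of visual angle
#'
#' Uses the linear small-angle convention
#' `deg = (px * cm_per_px / viewing_distance_cm) * 180 / pi`, the form that
#' reproduces printed field-of-view values for wide extents (46.5 degrees for
#' the full tablet width); it is exactly linear in `length_px`.
#'
#' @param length_px length in pixels (vectorised, must be >= 0).
#' @param display a [display_spec()].
#' @return degrees of visual angle.
#' @export
px_to_degrees <- function(length_px, display) {
  stopifnot(inherits(display, "display_spec"))
  if (any(length_px < 0)) stop("`length_px` must be non-negative", call. = FALSE)
  if (display$viewing_distance_cm <= 0) {
    stop("invalid geometry: non-positive viewing distance", call. = FALSE)
  }
  cm_per_px <- display$width_cm / display$width_px
  (length_px * cm_per_px / display$viewing_distance_cm) * 180 / pi
}

#' @rdname px_to_degrees
#' @param length_cm length in centimetres on the display surface.
#' @export
cm_to_degrees <- function(length_cm, display) {
  stopifnot(inherits(display, "display_spec"))
  (length_cm / display$viewing_distance_cm) * 180 / pi
}

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution per channel with reflective boundary
#' padding (avoids dark frames that would distort edge saliency).  Total
#' intensity is preserved up to boundary handling.
#'
#' @param image numeric matrix (grayscale) or 3-d array (H x W x channels).
#' @param sigma_px Gaussian sigma in pixels, > 0.
#' @return blurred image, same shape as the input.
#' @export
blur_image <- function(image, sigma_px) {
  stop_if_not_scalar_pos(sigma_px, "sigma_px")
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (is.matrix(image)) return(blur_matrix(image, sigma_px))
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- image
    for (k in seq_len(dim(image)[3])) out[, , k] <- blur_matrix(image[, , k], sigma_px)
    return(out)
  }
  stop("`image` must be a matrix or a 3-d array", call. = FALSE)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflective-padding indices for a dimension of size n and pad radius r.
reflect_idx <- function(n, r) {
  if (r >= n) {
    # fold repeatedly for tiny images
    idx <- seq_len(n + 2 * r) - r
    period <- 2 * n
    idx <- ((idx - 1) %% period + period) %% period + 1
    idx[idx > n] <- period - idx[idx > n] + 1
    return(idx)
  }
  c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
}

blur_matrix <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(x) {
    # convolve each column with k, reflective padding
    n <- nrow(x)
    xp <- x[reflect_idx(n, r), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[seq_len(n) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Composite a foveal aperture over a blurred image
#'
#' Per-pixel blend `out = a * native + (1 - a) * blurred` with Gaussian alpha
#' `a = exp(-d^2 / (2 * aperture_sigma_px^2))`, where `d` is the distance to
#' the aperture centre placed `vertical_offset_px` *above* the contact point
#' (screen convention: origin top-left, y grows downward, so "above" is
#' smaller y).
#'
#' @param native,blurred numeric matrices or 3-d arrays of identical shape.
#' @param contact_xy numeric length-2, the (x, y) contact point in 0-based
#'   pixel coordinates.
#' @param cfg a [render_config()].
#' @return composited image, same shape.
#' @export
composite_aperture <- function(native, blurred, contact_xy, cfg) {
  stopifnot(inherits(cfg, "render_config"), length(contact_xy) == 2L)
  if (!identical(dim(native), dim(blurred))) {
    stop("`native` and `blurred` must have identical shape", call. = FALSE)
  }
  d <- if (is.matrix(native)) dim(native) else dim(native)[1:2]
  h <- d[1]; w <- d[2]
  cx <- contact_xy[1]
  cy <- contact_xy[2] - cfg$vertical_offset_px
  xs <- (seq_len(w) - 1) - cx
  ys <- (seq_len(h) - 1) - cy
  d2 <- outer(ys^2, xs^2, `+`)
  a <- exp(-d2 / (2 * cfg$aperture_sigma_px^2))
  a <- pmin(a, 1)
  if (is.matrix(native)) return(a * native + (1 - a) * blurred)
  out <- native
  for (k in seq_len(dim(native)[3])) {
    out[, , k] <- a * native[, , k] + (1 - a) * blurred[, , k]
  }
  out
}

#' Exploration trajectory
#'
#' A regularly sampled finger (or gaze) trajectory: strictly increasing
#' sample times in seconds and 0-based pixel coordinates (origin top-left,
#' x rightward, y downward).
#'
#' @param t_s sample times, seconds, strictly increasing.
#' @param x_px,y_px pixel coordinates, same length as `t_s`.
#' @param display optional [display_spec()] the record was acquired on.
#' @param subject_id,image_id identifiers.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t_s, x_px, y_px, display = NULL,
                       subject_id = NA_character_, image_id = NA_character_) {
  n <- length(t_s)
  if (length(x_px) != n || length(y_px) != n) {
    stop("`t_s`, `x_px`, `y_px` must have equal length", call. = FALSE)
  }
  if (n > 1L && any(diff(t_s) <= 0)) {
    stop("`t_s` must be strictly increasing", call. = FALSE)
  }
  off <- rep(FALSE, n)
  if (!is.null(display)) {
    stopifnot(inherits(display, "display_spec"))
    off <- x_px < 0 | x_px > display$width_px - 1 |
      y_px < 0 | y_px > display$height_px - 1
  }
  structure(
    list(t_s = as.numeric(t_s), x_px = as.numeric(x_px),
         y_px = as.numeric(y_px), display = display,
         subject_id = subject_id, image_id = image_id,
         off_screen = off, under_threshold = FALSE),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> subject %s, image %s: %d samples over %.2f s, path %.0f px\n",
              x$subject_id, x$image_id, length(x$t_s),
              diff(range(x$t_s)), path_length(x)))
  invisible(x)
}

#' Cumulative Euclidean path length of a trajectory
#' @param traj a [trajectory()].
#' @return total path length in pixels.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(sqrt(diff(traj$x_px)^2 + diff(traj$y_px)^2))
}

#' Truncate a trajectory at a cumulative path-length threshold
#'
#' Implements the stopping rule of the foveated exploration task: the trial
#' ends when the cumulative distance travelled reaches a threshold.  Returns
#' the shortest prefix whose cumulative Euclidean path length reaches
#' `threshold_px`; if the full trajectory never reaches it, the whole
#' trajectory is returned with the `under_threshold` flag set.
#'
#' @param traj a [trajectory()] with at least 2 samples.
#' @param threshold_px path-length threshold in pixels.
#' @return a [trajectory()] (prefix of `traj`).
#' @export
truncate_at_path_threshold <- function(traj, threshold_px = 4000) {
  stopifnot(inherits(traj, "trajectory"))
  stop_if_not_scalar_pos(threshold_px, "threshold_px")
  n <- length(traj$t_s)
  if (n < 2L) stop("trajectory must have at least 2 samples", call. = FALSE)
  cum <- cumsum(c(0, sqrt(diff(traj$x_px)^2 + diff(traj$y_px)^2)))
  hit <- which(cum >= threshold_px)
  out <- traj
  if (length(hit) == 0L) {
    out$under_threshold <- TRUE
    return(out)
  }
  k <- hit[1]
  out$t_s <- traj$t_s[seq_len(k)]
  out$x_px <- traj$x_px[seq_len(k)]
  out$y_px <- traj$y_px[seq_len(k)]
  out$off_screen <- traj$off_screen[seq_len(k)]
  out$under_threshold <- FALSE
  out
}
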