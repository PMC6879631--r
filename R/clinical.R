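#' Mean similarity of a subject map to a reference set
#'
#' Mean Pearson correlation between a subject's attention map and each of a
#' set of reference maps for the same picture.  When the subject is one of
#' the references, exclude their own map from the reference set before
#' calling (leave-one-out).
#'
#' @param subject_map an [attention_map()].
#' @param reference_maps list of [attention_map()] on the same raster.
#' @return mean Pearson r.
#' @export
per_picture_similarity <- function(subject_map, reference_maps) {
  stopifnot(length(reference_maps) >= 1L)
  mean(vapply(reference_maps, function(r) map_correlation(subject_map, r),
              numeric(1)))
}

#' Build a neurotypical reference cohort
#'
#' From per-subject, per-picture attention maps of the reference population,
#' precompute everything needed to score new subjects: the reference maps
#' themselves, the per-picture mean and sd of the reference subjects'
#' leave-one-out similarities (first Z transform), and the mean and sd of
#' the reference subjects' across-picture average z (second Z transform).
#' By construction the cohort's own members score to sample mean 0 and sd 1.
#'
#' @param maps_by_subject named list (one element per reference subject) of
#'   named lists of [attention_map()] keyed by picture id.
#' @return An object of class `reference_cohort`.
#' @export
reference_cohort <- function(maps_by_subject) {
  S <- length(maps_by_subject)
  stopifnot(S >= 2L)
  pictures <- names(maps_by_subject[[1]])
  stopifnot(length(pictures) >= 1L)
  # per picture: LOO similarity of each reference subject
  sim <- matrix(NA_real_, nrow = S, ncol = length(pictures),
                dimnames = list(names(maps_by_subject), pictures))
  for (p in seq_along(pictures)) {
    pic <- pictures[p]
    pm <- lapply(maps_by_subject, `[[`, pic)
    for (s in seq_len(S)) {
      sim[s, p] <- per_picture_similarity(pm[[s]], pm[-s])
    }
  }
  pic_mean <- colMeans(sim)
  pic_sd <- apply(sim, 2, stats::sd)
  usable <- pic_sd > 0
  if (!all(usable)) {
    warning(sprintf("%d picture(s) with zero reference sd skipped",
                    sum(!usable)))
  }
  if (!any(usable)) stop("no usable picture in the cohort", call. = FALSE)
  z <- sweep(sweep(sim[, usable, drop = FALSE], 2, pic_mean[usable]),
             2, pic_sd[usable], `/`)
  avg_z <- rowMeans(z)
  structure(
    list(maps_by_subject = maps_by_subject, pictures = pictures,
         usable = usable, pic_mean = pic_mean, pic_sd = pic_sd,
         final_mean = mean(avg_z), final_sd = stats::sd(avg_z),
         ref_scores = (avg_z - mean(avg_z)) / stats::sd(avg_z)),
    class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat(sprintf("<reference_cohort> %d subjects, %d pictures (%d usable)\n",
              length(x$maps_by_subject), length(x$pictures), sum(x$usable)))
  invisible(x)
}

#' Exploration-neurotypicality score
#'
#' Double-Z deviation score of one subject against a neurotypical reference
#' cohort: per picture, the mean correlation with the reference maps is
#' z-scored using the cohort's per-picture reference distribution; the z
#' values are averaged across pictures; the average is z-scored again
#' against the cohort's distribution of averaged values.  Lower scores mean
#' a less typical exploration.
#'
#' @param subject_maps named list of [attention_map()] keyed by picture id
#'   (must share at least one usable picture with the cohort).
#' @param cohort a [reference_cohort()].
#' @param subject_id,group,method metadata for the returned record.
#' @return a one-row data.frame (`score_record`) with columns `subject_id`,
#'   `group`, `method`, `score`.
#' @export
neurotypicality_score <- function(subject_maps, cohort,
                                  subject_id = NA_character_,
                                  group = NA_character_,
                                  method = NA_character_) {
  stopifnot(inherits(cohort, "reference_cohort"))
  pics <- intersect(names(subject_maps), cohort$pictures[cohort$usable])
  if (length(pics) == 0L) stop("no usable picture in common with the cohort",
                               call. = FALSE)
  zs <- vapply(pics, function(pic) {
    refs <- lapply(cohort$maps_by_subject, `[[`, pic)
    s <- per_picture_similarity(subject_maps[[pic]], refs)
    (s - cohort$pic_mean[pic]) / cohort$pic_sd[pic]
  }, numeric(1))
  score <- (mean(zs) - cohort$final_mean) / cohort$final_sd
  data.frame(subject_id = subject_id, group = group, method = method,
             score = score, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of two score sets
#'
#' Two-sided rank-sum test; exact enumeration when both groups have at most
#' 10 observations and no ties, normal approximation with tie correction
#' otherwise.
#'
#' @param scoresA,scoresB numeric vectors, >= 3 each.
#' @return two-sided p-value.
#' @export
group_difference_test <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) >= 3L, length(scoresB) >= 3L)
  exact <- length(scoresA) <= 10 && length(scoresB) <= 10 &&
    !anyDuplicated(c(scoresA, scoresB))
  ht <- suppressWarnings(
    stats::wilcox.test(scoresA, scoresB, alternative = "two.sided",
                       exact = exact, correct = !exact))
  p <- ht$p.value
  # fully tied data degenerate the normal approximation (0/0): no evidence
  # of a difference
  if (!is.finite(p)) p <- 1
  p
}

#' Gaussian-kernel density fit of score distributions
#'
#' Fixed-sigma Gaussian kernel density (default sigma 0.6 score units),
#' evaluated on a grid spanning the data plus or minus 4 sigma (or a
#' supplied grid so two populations share a common support).  The grid
#' integral equals 1 within 1e-3.
#'
#' @param scores numeric vector, >= 2 values (or >= 1 if you accept a pure
#'   kernel bump).
#' @param kernel_sigma kernel sd in score units (default 0.6).
#' @param grid optional evaluation grid; built from the data when `NULL`.
#' @param n_grid grid resolution when `grid` is `NULL` (default 512).
#' @return An object of class `score_density` with fields `x`, `y`.
#' @export
fit_score_density <- function(scores, kernel_sigma = 0.6, grid = NULL,
                              n_grid = 512) {
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  stop_if_not_scalar_pos(kernel_sigma, "kernel_sigma")
  if (is.null(grid)) {
    grid <- seq(min(scores) - 4 * kernel_sigma,
                max(scores) + 4 * kernel_sigma, length.out = n_grid)
  }
  y <- vapply(grid, function(g) mean(stats::dnorm(g, scores, kernel_sigma)),
              numeric(1))
  structure(list(x = grid, y = y, kernel_sigma = kernel_sigma,
                 n = length(scores)),
            class = "score_density")
}

#' ROC curve and AUC from two fitted densities
#'
#' Threshold sweep over the common grid of two densities.  Orientation
#' follows the clinical convention used throughout the package: "positive"
#' is the atypical group and *lower* scores call positive, so sensitivity at
#' threshold t is the positive density's mass below t and the false-positive
#' rate is the negative density's mass below t.  AUC is computed by
#' trapezoidal integration of the (FPR, TPR) curve and lies in [0, 1].
#'
#' @param density_neg,density_pos `score_density` objects on a common grid
#'   (negative = typical, positive = atypical).
#' @return list with `roc` (data.frame: threshold, sensitivity,
#'   specificity) and `auc`.
#' @export
roc_from_densities <- function(density_neg, density_pos) {
  stopifnot(inherits(density_neg, "score_density"),
            inherits(density_pos, "score_density"))
  if (length(density_neg$x) != length(density_pos$x) ||
      max(abs(density_neg$x - density_pos$x)) > 1e-9) {
    stop("densities must share a common grid", call. = FALSE)
  }
  x <- density_neg$x
  cum_mass <- function(y) {
    n <- length(x)
    c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
  }
  Fn <- cum_mass(density_neg$y); Fn <- Fn / Fn[length(Fn)]
  Fp <- cum_mass(density_pos$y); Fp <- Fp / Fp[length(Fp)]
  tpr <- Fp   # positives called at score <= threshold
  fpr <- Fn
  auc <- trapz(fpr, tpr)
  list(roc = data.frame(threshold = x, sensitivity = tpr,
                        specificity = 1 - fpr),
       auc = auc)
}

#' Laterality index of an exploration session
#'
#' Fraction of exploration mass recorded right of the display midline
#' (x > width / 2), in percent: duration-weighted for fixation sets, sample
#' counts for trajectories.  When reference indices are supplied, a Z score
#' against the reference distribution and the corresponding normal centile
#' are reported; elevated right-side indices are the signature of left
#' hemispatial neglect.
#'
#' @param records list of [trajectory()] and/or [fixation_set()] objects
#'   from one session.
#' @param width_px display or raster width defining the midline.
#' @param reference optional numeric vector of reference subjects' indices
#'   (percent).
#' @return list with `pct_right`, and `z`, `centile` when a reference is
#'   given.
#' @export
laterality_index <- function(records, width_px, reference = NULL) {
  stopifnot(length(records) >= 1L)
  stop_if_not_scalar_pos(width_px, "width_px")
  mid <- width_px / 2
  right <- 0; total <- 0
  for (r in records) {
    if (inherits(r, "trajectory")) {
      right <- right + sum(r$x_px > mid)
      total <- total + length(r$x_px)
    } else if (inherits(r, "fixation_set")) {
      right <- right + sum(r$duration_ms[r$x_px > mid])
      total <- total + sum(r$duration_ms)
    } else {
      stop("records must be trajectories or fixation sets", call. = FALSE)
    }
  }
  if (total == 0) stop("no exploration mass", call. = FALSE)
  pct <- 100 * right / total
  out <- list(pct_right = pct)
  if (!is.null(reference)) {
    stopifnot(length(reference) >= 2L)
    out$z <- (pct - mean(reference)) / stats::sd(reference)
    out$centile <- 100 * stats::pnorm(out$z)
  }
  out
}
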