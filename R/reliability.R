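#' Inter-subject correlation of attention maps
#'
#' Mean Pearson correlation over all unordered pairs of subjects' attention
#' maps for one image.  Pairs involving a constant map are skipped with a
#' warning; if every pair is skipped an error is raised.
#'
#' @param maps list of per-subject [attention_map()] objects (same image,
#'   same raster), length >= 2.
#' @return the ISC value (scalar).
#' @export
inter_subject_correlation <- function(maps) {
  stopifnot(length(maps) >= 2L)
  n <- length(maps)
  vals <- numeric(0)
  skipped <- 0L
  vecs <- lapply(maps, function(m) as.vector(m$grid))
  const <- vapply(maps, `[[`, logical(1), "constant")
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (const[i] || const[j]) {
        skipped <- skipped + 1L
      } else {
        vals <- c(vals, stats::cor(vecs[[i]], vecs[[j]]))
      }
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d pair(s) skipped due to constant maps", skipped))
  }
  if (length(vals) == 0L) stop("all pairs skipped: no valid ISC", call. = FALSE)
  mean(vals)
}

#' Convergence-to-stability curve
#'
#' For each of `n_permutations` random orderings of the N subjects, compute
#' cumulative group maps of the first 1..N subjects; for n in 2..N record the
#' percent of variance of the n-subject map explained by the (n-1)-subject
#' map, as `100 * r^2` (Pearson r between the two cumulative maps).  The
#' returned curve averages the per-permutation curves.
#'
#' @param maps list of per-subject [attention_map()] objects, N >= 2.
#' @param n_permutations number of random subject orderings (default 40).
#' @param seed RNG seed (required for reproducibility).
#' @return An object of class `convergence_curve` with fields `n_values`
#'   (2..N) and `pct_variance`.
#' @export
convergence_curve <- function(maps, n_permutations = 40, seed) {
  N <- length(maps)
  stopifnot(N >= 2L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  curves <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      ord <- sample.int(N)
      prev <- NULL
      out <- numeric(N - 1L)
      for (n in seq_len(N)) {
        cur <- group_map(maps[ord[seq_len(n)]])
        if (n >= 2L) {
          r <- if (prev$constant || cur$constant) NA_real_ else
            stats::cor(as.vector(prev$grid), as.vector(cur$grid))
          out[n - 1L] <- 100 * r^2
        }
        prev <- cur
      }
      out
    }, numeric(N - 1L))
  })
  pct <- rowMeans(matrix(curves, nrow = N - 1L), na.rm = TRUE)
  structure(
    list(n_values = 2:N, pct_variance = pct, n_permutations = n_permutations,
         image_id = maps[[1]]$image_id, method = maps[[1]]$method),
    class = "convergence_curve")
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf("<convergence_curve> image %s (%s), %d permutations\n",
              x$image_id, x$method, x$n_permutations))
  print(stats::setNames(round(x$pct_variance, 2), x$n_values))
  invisible(x)
}

#' Minimal number of subjects for a variance level
#'
#' Smallest n whose percent-variance value exceeds `level` *and* stays above
#' it for every larger n (stability requirement: adding further subjects
#' keeps modifying less than `100 - level` percent of the variance).  If the
#' level is never stably exceeded, returns N with a `converged = FALSE`
#' attribute.
#'
#' @param curve a [convergence_curve()].
#' @param level percent-variance level (default 95).
#' @return integer subject count with attribute `converged`.
#' @export
min_subjects_for_variance <- function(curve, level = 95) {
  stopifnot(inherits(curve, "convergence_curve"))
  above <- curve$pct_variance > level
  # smallest n with all subsequent values above the level
  ok <- rev(cumprod(rev(above))) > 0
  if (any(ok)) {
    n <- curve$n_values[which(ok)[1]]
    return(structure(as.integer(n), converged = TRUE))
  }
  structure(as.integer(max(curve$n_values)), converged = FALSE)
}

#' Split-half stability of group attention maps
#'
#' Repeatedly draws two disjoint groups of `n` subjects, correlates their
#' group maps, and returns the mean correlation: how well n subjects predict
#' the map measured on n other subjects.
#'
#' @param maps list of per-subject [attention_map()] objects.
#' @param n group size; `2 * n` must not exceed the number of subjects.
#' @param n_resamples number of random splits (default 20).
#' @param seed RNG seed.
#' @return mean Pearson r across resamples.
#' @export
split_half_stability <- function(maps, n, n_resamples = 20, seed) {
  N <- length(maps)
  stop_if_not_scalar_pos(n, "n")
  if (2 * n > N) stop("2 * n exceeds the number of subjects", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rs <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      pick <- sample.int(N, 2 * n)
      g1 <- group_map(maps[pick[seq_len(n)]])
      g2 <- group_map(maps[pick[n + seq_len(n)]])
      if (g1$constant || g2$constant) return(NA_real_)
      stats::cor(as.vector(g1$grid), as.vector(g2$grid))
    }, numeric(1))
  })
  mean(rs, na.rm = TRUE)
}
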