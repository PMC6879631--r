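#' Read exploration records from CSV
#'
#' CSV contract (0-based, top-left pixel coordinates; times in seconds,
#' durations in milliseconds): header
#' `subject_id,image_id,t_s,x_px,y_px[,duration_ms]`.  Trajectory files
#' omit `duration_ms`; fixation files carry it (with `t_s` the onset).
#' Rows are validated; malformed files are rejected with the offending row
#' number.  Multiple subjects/images per file are allowed: the result is a
#' list of records split by (subject_id, image_id).
#'
#' @param path CSV file path.
#' @param kind `"trajectory"` or `"fixations"`.
#' @return list of [trajectory()] or [fixation_set()] objects.
#' @export
load_records <- function(path, kind = c("trajectory", "fixations")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_id", "t_s", "x_px", "y_px")
  if (kind == "fixations") need <- c(need, "duration_ms")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in c("t_s", "x_px", "y_px", intersect("duration_ms", names(df)))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing `%s` at row %d of %s", col,
                   bad[1], path), call. = FALSE)
    }
  }
  keys <- interaction(df$subject_id, df$image_id, drop = TRUE)
  lapply(split(seq_len(nrow(df)), keys), function(ix) {
    d <- df[ix, ]
    if (kind == "trajectory") {
      if (nrow(d) > 1L && any(diff(d$t_s) <= 0)) {
        bad <- ix[which(diff(d$t_s) <= 0)[1] + 1L]
        stop(sprintf("non-monotone t_s at row %d of %s", bad, path),
             call. = FALSE)
      }
      trajectory(d$t_s, d$x_px, d$y_px, subject_id = d$subject_id[1],
                 image_id = d$image_id[1])
    } else {
      fixation_set(d$x_px, d$y_px, d$t_s, d$duration_ms,
                   subject_id = d$subject_id[1], image_id = d$image_id[1])
    }
  })
}

#' @rdname load_records
#' @param records list of [trajectory()] / [fixation_set()] objects.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "trajectory") || inherits(records, "fixation_set")) {
    records <- list(records)
  }
  rows <- lapply(records, function(r) {
    if (inherits(r, "trajectory")) {
      data.frame(subject_id = r$subject_id, image_id = r$image_id,
                 t_s = r$t_s, x_px = r$x_px, y_px = r$y_px,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = r$subject_id, image_id = r$image_id,
                 t_s = r$onset_s, x_px = r$x_px, y_px = r$y_px,
                 duration_ms = r$duration_ms, stringsAsFactors = FALSE)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Transpose a record into the analysis space
#'
#' Affine scale-and-letterbox mapping of device coordinates into the common
#' analysis raster: the source frame is scaled (aspect ratio preserved) to
#' the largest size fitting the analysis rectangle and centred; points
#' outside the picture area are flagged off-screen.  All downstream
#' analyses then share one space and resolution.
#'
#' @param record a [trajectory()] or [fixation_set()].
#' @param source_wh source frame size `c(width, height)` in pixels.
#' @param analysis_raster target raster `c(width, height)` (default
#'   `c(1280, 1024)`).
#' @return the record with transposed coordinates (and, for trajectories,
#'   refreshed off-screen flags).
#' @export
transpose_to_analysis_space <- function(record, source_wh,
                                        analysis_raster = c(1280, 1024)) {
  sw <- source_wh[1]; sh <- source_wh[2]
  aw <- analysis_raster[1]; ah <- analysis_raster[2]
  s <- min(aw / sw, ah / sh)
  ox <- (aw - sw * s) / 2
  oy <- (ah - sh * s) / 2
  tx <- function(x) x * s + ox
  ty <- function(y) y * s + oy
  if (inherits(record, "trajectory")) {
    out <- record
    out$x_px <- tx(record$x_px); out$y_px <- ty(record$y_px)
    out$off_screen <- out$x_px < ox - 1e-9 | out$x_px > ox + sw * s + 1e-9 |
      out$y_px < oy - 1e-9 | out$y_px > oy + sh * s + 1e-9
    return(out)
  }
  if (inherits(record, "fixation_set")) {
    out <- record
    out$x_px <- tx(record$x_px); out$y_px <- ty(record$y_px)
    return(out)
  }
  stop("record must be a trajectory or fixation_set", call. = FALSE)
}

#' Write / read an attention map as portable text
#'
#' Dense tab-separated grid (rows = raster rows, top row first) next to a
#' JSON sidecar (`<path>.json`) holding shape and provenance metadata.
#'
#' @param map an [attention_map()].
#' @param path output path for the TSV grid.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "attention_map"))
  utils::write.table(map$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(width = ncol(map$grid), height = nrow(map$grid),
               n_subjects = map$n_subjects, method = map$method,
               image_id = map$image_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attention_map(grid, n_subjects = meta$n_subjects, method = meta$method,
                image_id = meta$image_id)
}

#' Export a grayscale image as plain PGM
#'
#' Plain-text portable graymap (P2), the text-only image format used for
#' rendered frames and heat-map inspection (no binary image codec is
#' assumed to be available).
#'
#' @param m numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param maxval gray levels (default 255).
#' @export
write_pgm <- function(m, path, maxval = 255) {
  stopifnot(is.matrix(m))
  v <- round(pmin(pmax(m, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", maxval)), con)
  utils::write.table(v, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline on a simulated or loaded dataset
#'
#' Orchestrates maps, reliability and scoring on a dataset shaped like the
#' output of [make_population()]: computes one attention map per (subject,
#' image), per-image inter-subject correlations, and — when a reference
#' group is named — exploration-neurotypicality scores of every non-
#' reference subject against a cohort built from the first
#' `reference_n` subjects of that group.  Outputs are deterministic given
#' (dataset, config); provenance (config, package version, config
#' checksum) is attached and written as a JSON sidecar when `out_dir` is
#' given.
#'
#' @param dataset list with `records` and `manifest` (see
#'   [make_population()]).
#' @param config list: `raster` (`c(width, height)`), `bandwidth_px`,
#'   optional `reference_group`, `reference_n` (default 10).
#' @param out_dir optional output directory for tidy CSVs + sidecar.
#' @return list with `maps` (named list `subject|image`), `isc`
#'   (data.frame), `scores` (data.frame or NULL), `provenance`.
#' @export
run_pipeline <- function(dataset, config, out_dir = NULL) {
  man <- dataset$manifest
  stopifnot(is.data.frame(man))
  raster <- config$raster %||% c(1280, 1024)
  bw <- config$bandwidth_px %||% 30
  maps <- list()
  for (i in seq_len(nrow(man))) {
    rec <- dataset$records[[man$record[i]]]
    m <- if (inherits(rec, "trajectory")) {
      map_from_trajectory(rec, bandwidth_px = bw, raster = raster)
    } else {
      map_from_fixations(rec, bandwidth_px = bw, raster = raster)
    }
    maps[[paste(man$subject_id[i], man$image_id[i], sep = "|")]] <- m
  }
  images <- unique(man$image_id)
  isc <- do.call(rbind, lapply(images, function(img) {
    subj <- man$subject_id[man$image_id == img]
    if (length(subj) < 2L) return(NULL)
    ms <- lapply(subj, function(s) maps[[paste(s, img, sep = "|")]])
    data.frame(image_id = img, statistic = "isc",
               value = inter_subject_correlation(ms),
               stringsAsFactors = FALSE)
  }))
  scores <- NULL
  if (!is.null(config$reference_group)) {
    n_ref <- config$reference_n %||% 10
    ref_sub <- unique(man$subject_id[man$group == config$reference_group])
    if (length(ref_sub) < n_ref) {
      stop("reference group too small for the requested cohort",
           call. = FALSE)
    }
    cohort_ids <- ref_sub[seq_len(n_ref)]
    by_subject <- function(sids) {
      stats::setNames(lapply(sids, function(s) {
        stats::setNames(lapply(images, function(img)
          maps[[paste(s, img, sep = "|")]]), images)
      }), sids)
    }
    cohort <- reference_cohort(by_subject(cohort_ids))
    test_ids <- setdiff(unique(man$subject_id), cohort_ids)
    scores <- do.call(rbind, lapply(test_ids, function(s) {
      grp <- man$group[man$subject_id == s][1]
      mode <- man$mode[man$subject_id == s][1]
      neurotypicality_score(by_subject(s)[[1]], cohort, subject_id = s,
                            group = grp, method = mode)
    }))
  }
  provenance <- list(
    package = "digitrack",
    version = as.character(utils::packageVersion("digitrack")),
    config = config,
    config_checksum = sum(utf8ToInt(paste(
      names(unlist(config)), unlist(config), collapse = ";"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(isc)) {
      utils::write.csv(isc, file.path(out_dir, "isc.csv"), row.names = FALSE)
    }
    if (!is.null(scores)) {
      utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  list(maps = maps, isc = isc, scores = scores, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
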