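#' Registration error from keypoint pairs
#'
#' The accuracy metric: the Euclidean distance between each pair of
#' corresponding landmarks (one marked on the RGB view, one on the
#' panorama, in the same coordinates), summarized by the median with
#' interquartile range. Quartiles use linear interpolation between order
#' statistics. Raw distances are kept in the report so any outlier
#' convention can be applied downstream; the listed outliers use the
#' conventional 1.5 IQR whisker rule.
#'
#' @param pairs data.frame with columns `x_rgb`, `y_rgb`, `x_pano`,
#'   `y_pano` (one landmark pair per row), or a numeric vector of
#'   precomputed distances.
#' @param image_width_px,section_width_mm optional scale for a mm
#'   conversion of the summary statistics (e.g. 960 px spanning 85 mm).
#' @return object of class `hsistitch_error_report`: list with
#'   `distances`, `n`, `median`, `q1`, `q3`, `max`, `outliers`, and — when
#'   a scale is given — `median_mm`, `q95_mm`, `mm_per_px`.
#' @export
registration_error <- function(pairs, image_width_px = NULL,
                               section_width_mm = NULL) {
  d <- if (is.numeric(pairs) && is.null(dim(pairs))) {
    pairs
  } else {
    stopifnot(all(c("x_rgb", "y_rgb", "x_pano", "y_pano") %in% names(pairs)))
    sqrt((pairs$x_rgb - pairs$x_pano)^2 + (pairs$y_rgb - pairs$y_pano)^2)
  }
  if (length(d) < 1L) stop("contract violation: at least one pair required")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  rep <- list(distances = d, n = length(d),
              median = q[2L], q1 = q[1L], q3 = q[3L], max = max(d),
              outliers = d[d > q[3L] + 1.5 * iqr])
  if (!is.null(image_width_px) && !is.null(section_width_mm)) {
    rep$mm_per_px <- section_width_mm / image_width_px
    rep$median_mm <- px_to_mm(q[2L], image_width_px, section_width_mm)
    rep$q95_mm <- px_to_mm(
      stats::quantile(d, 0.95, type = 7, names = FALSE),
      image_width_px, section_width_mm)
  }
  structure(rep, class = "hsistitch_error_report")
}

#' @export
print.hsistitch_error_report <- function(x, ...) {
  cat(sprintf(
    "<error report> n=%d median=%.2f px (IQR %.2f-%.2f), max=%.2f px\n",
    x$n, x$median, x$q1, x$q3, x$max))
  if (!is.null(x$median_mm)) {
    cat(sprintf("  at %.4f mm/px: median=%.3f mm, 95th pct=%.3f mm\n",
                x$mm_per_px, x$median_mm, x$q95_mm))
  }
  invisible(x)
}

#' Convert a pixel error to millimetres
#'
#' Cross-multiplication with the physical width of the imaged section: an
#' error of `e` px on an image `w` px wide spanning `s` mm corresponds to
#' `e * s / w` mm. At the reference working distance the 960 px wide view
#' spans 85 mm, so 2.2 px correspond to about 0.2 mm and 19.0 px to about
#' 1.7 mm.
#'
#' @param error_px error in pixels.
#' @param image_width_px image width in pixels (positive).
#' @param section_width_mm physical width of the imaged section in mm
#'   (positive).
#' @return error in millimetres.
#' @export
px_to_mm <- function(error_px, image_width_px, section_width_mm) {
  if (image_width_px <= 0 || section_width_mm <= 0) {
    stop("contract violation: widths must be positive")
  }
  error_px * section_width_mm / image_width_px
}

#' Automatic ground-truth registration error on a simulated scan
#'
#' Replaces manual landmark annotation with the simulator's ground truth:
#' scene points inside the scanned strip are mapped (a) through the
#' ground-truth transform chain into the panorama's global system and (b)
#' through the line homographies the pipeline actually used, and the
#' Euclidean displacement between the two placements is reported. Both
#' placements live in the line-plane global system (the offset translation
#' is common to both and cancels), so the distances are panorama pixels.
#'
#' @param result a [stitch_scan()] result.
#' @param gt the scan's `hsistitch_ground_truth`.
#' @param n_landmarks number of landmarks to sample.
#' @param seed integer seed for the sampler.
#' @param image_width_px,section_width_mm optional mm conversion scale.
#' @return a `hsistitch_error_report` (see [registration_error()]).
#' @export
auto_ground_truth_error <- function(result, gt, n_landmarks = 100L,
                                    seed = 0L, image_width_px = NULL,
                                    section_width_mm = NULL) {
  ll <- result$line_log
  if (nrow(ll) == 0L) stop("no stitched lines to evaluate")
  rng <- local_rng(seed)
  # global line system -> scene: first frame's placement carried to the
  # line plane by the calibration
  cal <- gt$calibration
  G0 <- gt$frame_H[[1L]] %*% cal$H_sens %*% cal$H_pos
  G0_inv <- solve(G0)
  max_attempts <- 20L * n_landmarks
  d <- numeric(0)
  attempts <- 0L
  state <- result$panorama
  while (length(d) < n_landmarks && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- ceiling(rng$runif(1L, 0, nrow(ll)))
    y <- rng$runif(1L, 10, 530)
    j <- ll$j[r]
    p_local <- c(0, y)
    # (a) truth: where this scene point belongs in the global system
    scene_pt <- hg_apply(gt$line_H[[j]], p_local)
    p_truth <- hg_apply(G0_inv, scene_pt)
    # (b) pipeline: where the pipeline placed it
    p_pipe <- hg_apply(line_log_H(ll, r), p_local)
    # landmark must fall on stitched canvas content (unless cropped away)
    if (!is.null(state$mask)) {
      cpt <- hg_apply(state$H_offset, p_pipe)
      xi <- round(cpt[1L]); yi <- round(cpt[2L])
      if (xi >= 0 && yi >= 0 && xi < ncol(state$mask) &&
          yi < nrow(state$mask) && !state$mask[yi + 1L, xi + 1L]) {
        next
      }
    }
    d <- c(d, sqrt(sum((p_pipe - p_truth)^2)))
  }
  if (length(d) == 0L) stop("no landmark fell on occupied panorama content")
  registration_error(d, image_width_px, section_width_mm)
}

#' Registration error as a function of scanning speed
#'
#' Runs one full simulate + stitch + evaluate cycle per speed on the same
#' scene and reports the error statistics per speed together with a linear
#' regression of mean error on speed (the error grows linearly with speed
#' for constant-velocity scans). A speed at which registration breaks down
#' (a reset, or too few stitched lines) is marked failed and excluded from
#' the regression.
#'
#' @param scene a [generate_scene()] result.
#' @param speeds numeric vector, scene px per frame interval.
#' @param n_frames frames per scan.
#' @param config a [stitch_config()].
#' @param noise_sd simulator noise.
#' @param seed integer seed.
#' @param n_landmarks landmarks per evaluation.
#' @return data.frame with columns `speed`, `median_px`, `mean_px`,
#'   `ok_frac`, `failed`; attributes `slope` and `intercept` hold the
#'   regression of mean error on speed over non-failed rows.
#' @export
speed_sweep <- function(scene, speeds, n_frames = 30L,
                        config = stitch_config(), noise_sd = 0,
                        seed = 0L, n_landmarks = 60L) {
  rows <- lapply(speeds, function(v) {
    traj <- make_trajectory("translation", n_frames, speed = v)
    scan <- simulate_scan(scene, traj, noise_sd = noise_sd, seed = seed)
    res <- stitch_scan(ingest(scan), config = config)
    n_expected <- (n_frames - 1L) * 7L
    failed <- res$n_resets > 0L || nrow(res$line_log) < 0.5 * n_expected
    if (failed) {
      return(data.frame(speed = v, median_px = NA_real_,
                        mean_px = NA_real_, ok_frac = mean(
                          res$frame_log$verdict == "ok", na.rm = TRUE),
                        failed = TRUE))
    }
    er <- auto_ground_truth_error(res, scan$gt, n_landmarks, seed = seed)
    data.frame(speed = v, median_px = er$median,
               mean_px = mean(er$distances),
               ok_frac = mean(res$frame_log$verdict == "ok", na.rm = TRUE),
               failed = FALSE)
  })
  out <- do.call(rbind, rows)
  okr <- out[!out$failed, , drop = FALSE]
  if (nrow(okr) >= 2L && length(unique(okr$speed)) >= 2L) {
    fit <- stats::lm(mean_px ~ speed, data = okr)
    attr(out, "slope") <- unname(stats::coef(fit)[2L])
    attr(out, "intercept") <- unname(stats::coef(fit)[1L])
  }
  out
}

#' Read manually annotated landmark pairs
#'
#' Annotation pairs are consumed as CSV with columns `frame`, `x_rgb`,
#' `y_rgb`, `x_pano`, `y_pano`.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [registration_error()].
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_rgb", "y_rgb", "x_pano", "y_pano")
  if (!all(need %in% names(df))) {
    stop("pairs file must contain columns ", paste(need, collapse = ", "))
  }
  df
}
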