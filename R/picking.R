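#' Default pipeline configuration
#'
#' All tunable parameters of the registration and stitching stages, with the
#' pipeline's empirical defaults: 1000 keypoints per frame, Lowe ratio 0.8,
#' RANSAC confidence 0.995 with an 8.0 px reprojection threshold, at least
#' 40 inlier matches per plausible homography, panorama reset after 20
#' consecutive invalid frames, database caps of 500 ranked matches / 50 new
#' entries / 200 descriptor updates / age limit 80, inter-stream delay 35
#' ms, adaptive line width capped at 8 px (fixed width 3 px when the
#' adaptive feature is off), and a 100 px forget margin beyond the display
#' window.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
stitch_config <- function(...) {
  cfg <- list(
    max_keypoints = 1000L,
    lowe_ratio = 0.8,
    ransac_confidence = 0.995,
    ransac_threshold_px = 8.0,
    min_inliers = 40L,
    min_motion_px = 2,
    max_motion_frac = 0.25,
    area_ratio_range = c(0.5, 2.0),
    max_invalid = 20L,
    max_matches = 500L,
    max_new = 50L,
    max_updates = 200L,
    max_age = 80L,
    delta_ms = 35,
    adaptive_width = TRUE,
    fixed_width = 3L,
    width_cap = 8L,
    forget_margin = 100,
    false_color = "gray",
    band_rgb = c(620, 550, 500),
    seed = 0L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Estimate a homography from keypoint matches
#'
#' Robust RANSAC estimation of the homography mapping matched keypoints of
#' the current set onto their counterparts in the reference set (the
#' reference frame's origin is the reference for the transformation).
#'
#' @param matches a [match_descriptors()] result.
#' @param current,reference the matched keypoint sets.
#' @param confidence,reproj_threshold RANSAC parameters (defaults 0.995 and
#'   8.0 px).
#' @param seed integer RANSAC seed.
#' @return list with `H` (3x3 or `NULL`), `inliers` (logical per match),
#'   `n_inliers`, `ok` (FALSE when fewer than 4 matches were available or
#'   estimation degenerated — a `low_inliers` signal).
#' @export
estimate_homography <- function(matches, current, reference,
                                confidence = 0.995, reproj_threshold = 8.0,
                                seed = 0L) {
  if (nrow(matches) < 4L) {
    return(list(H = NULL, inliers = logical(nrow(matches)), n_inliers = 0L,
                ok = FALSE))
  }
  src <- current$xy[matches$current, , drop = FALSE]
  dst <- reference$xy[matches$reference, , drop = FALSE]
  fit <- hg_ransac(src, dst, confidence = confidence,
                   threshold = reproj_threshold, seed = seed)
  fit$ok <- !is.null(fit$H)
  fit
}

# corner geometry of a warped w x h frame rectangle
warped_corner_stats <- function(H, width, height) {
  corners <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  wp <- tryCatch(hg_apply(H, corners), error = function(e) NULL)
  if (is.null(wp) || any(!is.finite(wp))) return(NULL)
  disp <- sqrt(rowSums((wp - corners)^2))
  # signed area (shoelace) of the warped quadrilateral, vertices in order
  xs <- wp[, 1L]; ys <- wp[, 2L]
  area2 <- sum(xs * ys[c(2:4, 1L)] - xs[c(2:4, 1L)] * ys)
  # convexity with preserved orientation: all cross products positive
  # (original corner order is clockwise in image coords -> positive z)
  cross_z <- vapply(1:4, function(i) {
    a <- wp[i, ]; b <- wp[i %% 4L + 1L, ]; c <- wp[(i + 1L) %% 4L + 1L, ]
    (b[1L] - a[1L]) * (c[2L] - b[2L]) - (b[2L] - a[2L]) * (c[1L] - b[1L])
  }, numeric(1L))
  list(max_disp = max(disp), area_ratio = (area2 / 2) / (width * height),
       convex_same_orientation = all(cross_z > 0))
}

#' Plausibility gate for an estimated homography
#'
#' Applies the three quality objectives in order: sufficient image motion
#' (maximum corner displacement at least `min_motion_px`, otherwise the
#' frame is skipped as `no_motion` without counting as invalid), a
#' sufficient number of inlier matches (40 by default), no excessive
#' displacement (corner displacement above `max_motion_frac` of the frame
#' width), and no abnormal distortion (warped corner quadrilateral must stay
#' convex with preserved orientation and keep its area within
#' `area_ratio_range` of the original).
#'
#' @param H estimated homography, or `NULL` for an estimation failure.
#' @param inlier_count number of RANSAC inliers.
#' @param frame_size `c(width, height)` in pixels.
#' @param config a [stitch_config()].
#' @return character verdict: one of `"ok"`, `"no_motion"`, `"low_inliers"`,
#'   `"excessive_motion"`, `"distorted"`.
#' @export
gate_frame <- function(H, inlier_count, frame_size = c(960L, 540L),
                       config = stitch_config()) {
  if (is.null(H)) return("low_inliers")
  st <- warped_corner_stats(H, frame_size[1L], frame_size[2L])
  if (is.null(st)) return("distorted")
  if (st$max_disp < config$min_motion_px) return("no_motion")
  if (inlier_count < config$min_inliers) return("low_inliers")
  # distortion is checked before excessive motion: an orientation flip or
  # area blow-up also displaces corners, but is the more specific failure
  if (!st$convex_same_orientation ||
      st$area_ratio < config$area_ratio_range[1L] ||
      st$area_ratio > config$area_ratio_range[2L]) {
    return("distorted")
  }
  if (st$max_disp > config$max_motion_frac * frame_size[1L]) {
    return("excessive_motion")
  }
  "ok"
}

# invalid-attempt counter: `ok` zeroes it, `no_motion` leaves it untouched,
# everything else increments; returns the new count and whether the
# panorama must be reset (fires exactly when the count reaches the cap)
update_invalid_counter <- function(count, verdict, max_invalid = 20L) {
  if (verdict == "ok") {
    return(list(count = 0L, reset = FALSE))
  }
  if (verdict == "no_motion") {
    return(list(count = count, reset = FALSE))
  }
  count <- count + 1L
  if (count >= max_invalid) {
    list(count = 0L, reset = TRUE)
  } else {
    list(count = count, reset = FALSE)
  }
}
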