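#' Panorama keypoint database
#'
#' The global registration stage avoids re-extracting features from the
#' whole panorama by keeping a bounded store of its strongest keypoints
#' since sequence start: global coordinates (the system set by the
#' upper-left corner of the first incoming RGB frame, unchanged
#' thereafter), 256-bit descriptors, and an unmatched-age counter per
#' entry. Growth is regulated by four caps (see [stitch_config()]):
#' only the 500 best-ranked matches feed the homography, at most the 50
#' strongest unmatched keypoints are added per frame, at most the 200
#' lowest-distance inlier matches have coordinates and descriptors
#' refreshed, and entries that fail to match for more than 80 processed
#' frames are evicted.
#'
#' @return `keypoint_db()` returns an empty database of class
#'   `hsistitch_db`.
#' @export
keypoint_db <- function() {
  structure(
    list(xy = matrix(numeric(0), 0L, 2L,
                     dimnames = list(NULL, c("x", "y"))),
         desc = matrix(0L, 0L, 256L),
         age = integer(0),
         started = FALSE),
    class = "hsistitch_db"
  )
}

db_size <- function(db) nrow(db$xy)

#' @export
print.hsistitch_db <- function(x, ...) {
  cat(sprintf("<hsistitch_db> %d entries, started=%s\n", db_size(x),
              x$started))
  invisible(x)
}

# bootstrap: seed the database with the first frame's keypoints at their
# frame coordinates (H_(1,P) is the identity by construction)
db_bootstrap <- function(db, keypoints) {
  db$xy <- keypoints$xy
  db$desc <- keypoints$desc
  db$age <- integer(n_keypoints(keypoints))
  db$started <- TRUE
  db
}

#' Match a frame's keypoints against the panorama database
#'
#' Brute-force Hamming matching (same matcher as the frame-to-frame stage)
#' followed by ranking: only the `max_matches` lowest-distance matches (500
#' by default) are forwarded to homography estimation.
#'
#' @param current `hsistitch_keypoints` of the current frame.
#' @param db a `hsistitch_db`.
#' @param max_matches ranking cap.
#' @param ratio Lowe's ratio used by the matcher.
#' @return `hsistitch_matches` data.frame (`current` indexes the frame set,
#'   `reference` indexes database entries).
#' @export
global_match <- function(current, db, max_matches = 500L, ratio = 0.8) {
  if (!db$started || db_size(db) == 0L) {
    stop("reset-required: keypoint database is empty on a non-first frame")
  }
  m <- match_descriptors(current, structure(
    list(xy = db$xy, response = rep(0, db_size(db)), desc = db$desc),
    class = "hsistitch_keypoints"), ratio = ratio)
  if (nrow(m) > max_matches) {
    keep <- order(m$distance)[seq_len(max_matches)]
    m <- m[sort(keep), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Estimate the global frame-to-panorama homography
#'
#' Same RANSAC estimator and plausibility gate as the frame-to-frame stage,
#' applied to matches between the current frame and the database. Because
#' the global homography legitimately accumulates the whole scan's motion,
#' the gate inspects the *incremental* transform relative to the previous
#' accepted global homography; the minimal-motion check is disabled here
#' (low motion is already filtered frame-to-frame).
#'
#' @param matches a [global_match()] result.
#' @param current the frame's keypoints.
#' @param db the database.
#' @param H_prev_global previous accepted global homography (identity at
#'   sequence start).
#' @param config a [stitch_config()].
#' @param seed RANSAC seed.
#' @return list with `H` (frame-to-panorama), `inliers`, `n_inliers`,
#'   `verdict`.
#' @export
estimate_global <- function(matches, current, db,
                            H_prev_global = hg_identity(),
                            config = stitch_config(), seed = 0L) {
  db_kp <- structure(
    list(xy = db$xy, response = rep(0, db_size(db)), desc = db$desc),
    class = "hsistitch_keypoints")
  fit <- estimate_homography(matches, current, db_kp,
                             confidence = config$ransac_confidence,
                             reproj_threshold = config$ransac_threshold_px,
                             seed = seed)
  if (!fit$ok) {
    fit$verdict <- "low_inliers"
    return(fit)
  }
  delta <- tryCatch(solve(H_prev_global) %*% fit$H, error = function(e) NULL)
  gate_cfg <- config
  gate_cfg$min_motion_px <- 0
  fit$verdict <- if (is.null(delta)) "distorted" else {
    gate_frame(delta, fit$n_inliers, c(960L, 540L), gate_cfg)
  }
  fit
}

#' Database maintenance after a processed frame
#'
#' Applies the per-keypoint outcome rules: unmatched frame keypoints are
#' considered new and the `max_new` strongest are added with coordinates
#' warped into the global system by the frame's global homography; inlier
#' matches refresh their entry (the `max_updates` with the lowest Hamming
#' distance get warped current coordinates and the current descriptor,
#' every inlier gets its age zeroed); outlier matches — or any match that
#' participated in an implausible homography — are discarded as uncertainty
#' factors. All remaining entries age by one frame and entries older than
#' `max_age` are evicted. When the frame as a whole was discarded
#' (`verdict != "ok"`) only the discard rule runs.
#'
#' @param db the database.
#' @param current the frame's keypoints.
#' @param matches the [global_match()] result used for estimation.
#' @param inliers logical inlier mask per match row.
#' @param H accepted global homography (frame to panorama), used to warp
#'   coordinates; ignored for discarded frames.
#' @param verdict the gate verdict for this frame.
#' @param config a [stitch_config()].
#' @return the updated database.
#' @export
db_maintain <- function(db, current, matches, inliers, H, verdict,
                        config = stitch_config()) {
  n <- db_size(db)
  if (verdict != "ok") {
    # rule (c) only: matched entries of an implausible homography go away
    if (nrow(matches) > 0L) {
      drop <- unique(matches$reference)
      keep <- setdiff(seq_len(n), drop)
      db$xy <- db$xy[keep, , drop = FALSE]
      db$desc <- db$desc[keep, , drop = FALSE]
      db$age <- db$age[keep]
    }
    return(db)
  }
  matched_ref <- matches$reference
  inlier_ref <- matched_ref[inliers]
  outlier_ref <- matched_ref[!inliers]
  inlier_cur <- matches$current[inliers]
  inlier_dist <- matches$distance[inliers]

  # (b) inlier updates: the `max_updates` lowest-distance matches carry the
  # current detection (warped) and descriptor; every inlier entry rejuvenates
  upd_sel <- integer(0)
  if (length(inlier_ref)) {
    ord <- order(inlier_dist)
    upd_sel <- ord[seq_len(min(config$max_updates, length(ord)))]
    warped <- hg_apply(H, current$xy[inlier_cur[upd_sel], , drop = FALSE])
    db$xy[inlier_ref[upd_sel], ] <- warped
    db$desc[inlier_ref[upd_sel], ] <- current$desc[inlier_cur[upd_sel], ,
                                                   drop = FALSE]
  }

  # (d) ageing: every entry ages except inlier-matched ones (age zeroed)
  db$age <- db$age + 1L
  if (length(inlier_ref)) db$age[inlier_ref] <- 0L

  # (c) discard outlier matches
  keep <- setdiff(seq_len(n), unique(outlier_ref))
  # age eviction
  keep <- keep[db$age[keep] <= config$max_age]
  db$xy <- db$xy[keep, , drop = FALSE]
  db$desc <- db$desc[keep, , drop = FALSE]
  db$age <- db$age[keep]

  # (a) additions: the strongest unmatched current keypoints, warped
  unmatched <- setdiff(seq_len(n_keypoints(current)), matches$current)
  if (length(unmatched)) {
    ord <- unmatched[order(current$response[unmatched], decreasing = TRUE)]
    add <- ord[seq_len(min(config$max_new, length(ord)))]
    db$xy <- rbind(db$xy, hg_apply(H, current$xy[add, , drop = FALSE]))
    db$desc <- rbind(db$desc, current$desc[add, , drop = FALSE])
    db$age <- c(db$age, integer(length(add)))
  }
  db
}

#' Serialize a keypoint database to JSON
#'
#' @param db a `hsistitch_db`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
db_to_json <- function(db, path = NULL) {
  obj <- list(started = db$started,
              x = db$xy[, 1L], y = db$xy[, 2L],
              age = db$age,
              desc = apply(db$desc, 1L, paste0, collapse = ""))
  if (db_size(db) == 0L) obj$desc <- character(0)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
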