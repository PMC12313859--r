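#' Run the full stitching pipeline on a scan
#'
#' Drives every stage over the two preprocessed streams: keypoint
#' extraction, frame-to-frame registration with plausibility gating,
#' frame-to-panorama registration against the bounded keypoint database,
#' database maintenance, temporal line selection, homography interpolation
#' and conjugation, adaptive line widening, newest-wins compositing with
#' offset handling, and the forget-function crop. After 20 consecutive
#' invalid frames the panorama is reset and a new stitching sequence
#' begins with the next frame.
#'
#' @param streams an [ingest()] result (or a `hsistitch_scan`, which is
#'   ingested with default settings).
#' @param config a [stitch_config()].
#' @param gt optional `hsistitch_ground_truth`; required when
#'   `use_gt_homographies` is `TRUE`.
#' @param use_gt_homographies bypass registration and drive the stitching
#'   stage with ground-truth global homographies (isolates compositing
#'   accuracy from registration accuracy).
#' @param keep_frames retain the preprocessed frames in the result (needed
#'   for overlay rendering afterwards).
#' @return object of class `hsistitch_result`: list with
#'   \describe{
#'     \item{panorama}{final `hsistitch_panorama` state.}
#'     \item{frame_log}{data.frame per frame: `index`, `t`, `stage`,
#'       `verdict`, `inliers_local`, `inliers_global`, `reset`.}
#'     \item{line_log}{data.frame per stitched line: `j` (1-based index
#'       into the line stream), `width`, plus the line-plane global
#'       homography rows `h11..h33`.}
#'     \item{n_resets}{number of panorama resets.}
#'   }
#' @export
stitch_scan <- function(streams, config = stitch_config(), gt = NULL,
                        use_gt_homographies = FALSE, keep_frames = FALSE) {
  if (inherits(streams, "hsistitch_scan")) streams <- ingest(streams)
  frames <- streams$frames
  cal <- streams$calibration
  n <- length(frames)
  lt <- streams$lines$t
  buffer <- data.frame(j = seq_along(lt), t = lt)

  if (use_gt_homographies && is.null(gt)) {
    stop("ground truth required when bypassing registration")
  }

  db <- keypoint_db()
  state <- panorama_state()
  seq_start <- TRUE
  H_prev_global <- hg_identity()
  H_prime_prev <- hg_identity()
  prev_kp <- NULL
  t_prev <- NA_real_
  invalid <- 0L
  n_resets <- 0L
  H1_gt <- NULL  # gt frame->scene of the sequence's first frame

  log_rows <- vector("list", n)
  line_rows <- list()

  for (i in seq_len(n)) {
    fr <- frames[[i]]
    verdict <- NA_character_
    stage <- NA_character_
    inl_l <- NA_integer_
    inl_g <- NA_integer_
    reset <- FALSE

    if (use_gt_homographies) {
      kp <- NULL
    } else {
      kp <- extract_keypoints(fr, config$max_keypoints)
    }

    if (seq_start) {
      if (!use_gt_homographies) db <- db_bootstrap(db, kp)
      H_prev_global <- hg_identity()
      H_prime_prev <- hg_identity()
      prev_kp <- kp
      t_prev <- fr$t
      seq_start <- FALSE
      if (use_gt_homographies) H1_gt <- gt$frame_H[[i]]
      log_rows[[i]] <- data.frame(index = fr$index, t = fr$t,
                                  stage = "bootstrap", verdict = "ok",
                                  inliers_local = NA_integer_,
                                  inliers_global = NA_integer_,
                                  reset = FALSE)
      next
    }

    if (use_gt_homographies) {
      H_global <- hg_normalize(solve(H1_gt) %*% gt$frame_H[[i]])
      verdict <- "ok"
      stage <- "ground_truth"
      matches_g <- NULL
      fit_g <- list(H = H_global, inliers = logical(0), n_inliers = NA_integer_)
    } else {
      # --- local picking stage -------------------------------------------
      m_local <- match_descriptors(kp, prev_kp, config$lowe_ratio)
      fit_l <- estimate_homography(
        m_local, kp, prev_kp,
        confidence = config$ransac_confidence,
        reproj_threshold = config$ransac_threshold_px,
        seed = config$seed + 7L * i)
      inl_l <- fit_l$n_inliers
      v_local <- gate_frame(fit_l$H, fit_l$n_inliers,
                            c(ncol(fr$image), nrow(fr$image)), config)
      if (v_local != "ok") {
        stage <- "local"
        verdict <- v_local
      } else {
        # --- global registration stage -----------------------------------
        matches_g <- global_match(kp, db, config$max_matches,
                                  config$lowe_ratio)
        fit_g <- estimate_global(matches_g, kp, db, H_prev_global, config,
                                 seed = config$seed + 7L * i + 3L)
        inl_g <- fit_g$n_inliers
        stage <- "global"
        verdict <- fit_g$verdict
        db <- db_maintain(db, kp, matches_g, fit_g$inliers, fit_g$H,
                          verdict, config)
      }
      H_global <- if (verdict == "ok") hg_normalize(fit_g$H) else NULL
    }

    upd <- update_invalid_counter(invalid, verdict, config$max_invalid)
    invalid <- upd$count
    if (upd$reset) {
      reset <- TRUE
      n_resets <- n_resets + 1L
      db <- keypoint_db()
      state <- panorama_state()
      seq_start <- TRUE
      prev_kp <- NULL
    }

    if (verdict == "ok" && !is.na(verdict)) {
      # --- line stitching stage ------------------------------------------
      sel <- select_lines(buffer, t_prev, fr$t, config$delta_ms)
      buffer <- sel$buffer
      set <- sel$set
      nl <- nrow(set)
      if (nl >= 1L) {
        H_interp <- interpolate_homographies(H_prev_global, H_global, nl)
        H_primes <- lapply(H_interp, function(h) {
          hg_normalize(adjust_for_line(h, cal$H_sens, cal$H_pos))
        })
        H_prime_cur <- adjust_for_line(H_global, cal$H_sens, cal$H_pos)
        dH <- frame_delta(H_prime_prev, H_prime_cur)
        wdt <- adaptive_width(dH, 540L, nl, config$width_cap,
                              config$adaptive_width, config$fixed_width)
        dir <- motion_direction(dH)
        colors <- lapply(seq_len(nl), function(k) {
          false_color(streams$lines$data[set$j[k], , ],
                      config$false_color, config$band_rgb)
        })
        state <- warp_and_composite(colors, H_primes, rep(wdt, nl),
                                    rep(dir, nl), state)
        line_rows[[length(line_rows) + 1L]] <- data.frame(
          j = set$j, width = wdt,
          do.call(rbind, lapply(H_primes, function(h) {
            stats::setNames(as.data.frame(t(as.vector(t(h)))),
                            c("h11", "h12", "h13", "h21", "h22", "h23",
                              "h31", "h32", "h33"))
          })))
      }
      # forget-function crop around the current display window
      if (!is.null(state$mask) && is.finite(config$forget_margin)) {
        W <- state$H_offset %*% solve(cal$H_pos) %*% solve(cal$H_sens) %*%
          H_global
        fc <- hg_apply(W, rbind(c(0, 0), c(959, 0), c(0, 539), c(959, 539)))
        state <- crop_forget(state,
                             list(xmin = min(fc[, 1L]), xmax = max(fc[, 1L]),
                                  ymin = min(fc[, 2L]), ymax = max(fc[, 2L])),
                             config$forget_margin)
      }
      H_prev_global <- H_global
      H_prime_prev <- adjust_for_line(H_global, cal$H_sens, cal$H_pos)
      t_prev <- fr$t
      prev_kp <- kp
    }
    log_rows[[i]] <- data.frame(index = fr$index, t = fr$t, stage = stage,
                                verdict = verdict, inliers_local = inl_l,
                                inliers_global = inl_g, reset = reset)
  }

  res <- list(
    panorama = state,
    frame_log = do.call(rbind, log_rows),
    line_log = if (length(line_rows)) do.call(rbind, line_rows) else
      data.frame(j = integer(0), width = integer(0)),
    n_resets = n_resets,
    config = config,
    calibration = cal,
    db = db
  )
  if (keep_frames) res$frames <- frames
  structure(res, class = "hsistitch_result")
}

#' @export
print.hsistitch_result <- function(x, ...) {
  ok <- sum(x$frame_log$verdict == "ok", na.rm = TRUE)
  cat(sprintf(
    "<hsistitch_result> %d frames (%d ok), %d lines stitched, %d resets\n",
    nrow(x$frame_log), ok, nrow(x$line_log), x$n_resets))
  invisible(x)
}

# recover a stitched line's line-plane global homography from the log
line_log_H <- function(line_log, row) {
  matrix(as.numeric(line_log[row, c("h11", "h12", "h13", "h21", "h22",
                                    "h23", "h31", "h32", "h33")]),
         3L, 3L, byrow = TRUE)
}
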