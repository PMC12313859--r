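#' Fixed spectral synthesis profile
#'
#' The synthetic scanner expands a scalar scene albedo `a` into a 100-band
#' spectrum `a * s(lambda)` where `s` is a fixed smooth profile with unit
#' mean over the bands (500-1000 nm at 5 nm spacing). Unit mean makes the
#' band-mean (grayscale) false-color mapping an exact inverse of the
#' synthesis, so a stitched grayscale panorama can be compared pixel by
#' pixel against the scene albedo itself.
#'
#' @return numeric vector of length 100 with `mean(s) == 1`.
#' @export
spectral_profile <- function() {
  lam <- seq(0, 1, length.out = 100L)
  s <- 1 + 0.35 * cos(2 * pi * lam) + 0.1 * sin(4 * pi * lam)
  s / mean(s)
}

#' Band wavelengths of the simulated spectrograph
#' @return numeric vector, nanometres.
#' @export
band_wavelengths <- function() seq(500, 995, by = 5)

#' Simulate an asynchronous dual-sensor scan
#'
#' Emulates the laparoscope's two raw streams from a planar scene under a
#' known camera trajectory: 960x540 RGB frames at `rgb_fps` (nominally 10)
#' and one-pixel-wide, 540-tall, 100-band spectral lines at `hsi_fps`
#' (nominally 70), so about 7 lines fall between consecutive frames. Frames
#' are crops of the scene under the interpolated pose (optionally
#' barrel-distorted and vignetted per the calibration); each line is the
#' scene column under the slit at its timestamp, expanded spectrally by
#' [spectral_profile()]. Emitted line timestamps are shifted by `-delay_ms`
#' relative to truth, so the pipeline's `+delta` correction re-synchronizes
#' them. All timestamps are integer milliseconds from scan start.
#'
#' @param scene a [generate_scene()] result.
#' @param trajectory a [make_trajectory()] result (one pose per RGB frame).
#' @param rgb_fps,hsi_fps stream rates in Hz; `rgb_fps <= hsi_fps`.
#' @param delay_ms inter-stream delay applied to emitted line timestamps.
#' @param calibration a [calibration_bundle()]; identity geometry and zero
#'   distortion by default.
#' @param noise_sd Gaussian pixel noise s.d. (intensity units in `[0, 1]`).
#' @param seed integer seed for the noise.
#' @return object of class `hsistitch_scan`: list with
#'   \describe{
#'     \item{frames}{list of `TimedFrame`s: `image` (540x960 matrix of 8-bit
#'       intensities), `t` (ms), `index`.}
#'     \item{lines}{list: `data` (J x 540 x 100 array), `t` (emitted ms).}
#'     \item{gt}{`ScanGroundTruth`: per-frame frame-to-scene homographies,
#'       per-line line-to-scene homographies at the delay-corrected time,
#'       the delay and calibration used.}
#'   }
#' @export
simulate_scan <- function(scene, trajectory, rgb_fps = 10, hsi_fps = 70,
                          delay_ms = 35, calibration = calibration_bundle(),
                          noise_sd = 0, seed = 0L) {
  stopifnot(inherits(scene, "hsistitch_scene"),
            inherits(trajectory, "hsistitch_trajectory"),
            rgb_fps <= hsi_fps, rgb_fps > 0)
  fw <- 960L; fh <- 540L
  n_frames <- nrow(trajectory$poses)
  frame_t <- as.integer(round((seq_len(n_frames) - 1L) * 1000 / rgb_fps))
  duration_ms <- n_frames * 1000 / rgb_fps
  n_lines <- as.integer(floor(duration_ms / 1000 * hsi_fps))
  line_t_true <- as.integer(round((seq_len(n_lines) - 1L) * 1000 / hsi_fps))
  line_t <- line_t_true - as.integer(round(delay_ms))
  ms_per_frame <- 1000 / rgb_fps

  sw <- ncol(scene$albedo); sh <- nrow(scene$albedo)
  H_line <- calibration$H_sens %*% calibration$H_pos

  # field-of-view check over frames and line placements
  corners <- rbind(c(0, 0), c(fw - 1, 0), c(0, fh - 1), c(fw - 1, fh - 1))
  check_inside <- function(H, t) {
    p <- hg_apply(H, corners)
    if (any(p[, 1L] < 0) || any(p[, 1L] > sw - 1) ||
        any(p[, 2L] < 0) || any(p[, 2L] > sh - 1)) {
      stop(sprintf(
        "simulation error: trajectory leaves the scene at t = %d ms", t))
    }
  }
  frame_H <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    frame_H[[i]] <- pose_homography(trajectory$poses[i, ], fw, fh)
    check_inside(frame_H[[i]], frame_t[i])
  }
  line_H <- vector("list", n_lines)
  for (j in seq_len(n_lines)) {
    u <- line_t_true[j] / ms_per_frame
    Hf <- pose_homography(interp_pose(trajectory, u), fw, fh)
    check_inside(Hf, line_t_true[j])
    line_H[[j]] <- Hf %*% H_line
  }

  rng <- local_rng(seed)

  # render frames: raw pixel -> (inverse distortion) -> frame coords ->
  # scene coords -> bilinear albedo
  xs <- rep(seq_len(fw) - 1, each = fh)
  ys <- rep(seq_len(fh) - 1, times = fw)
  und <- undistort_points(calibration, xs, ys)
  vig <- if (calibration$vignette > 0) {
    r2 <- ((xs - (fw - 1) / 2) / (fw / 2))^2 +
      ((ys - (fh - 1) / 2) / (fw / 2))^2
    1 - calibration$vignette * r2
  } else NULL
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    p <- cbind(und$x, und$y, 1) %*% t(frame_H[[i]])
    w <- p[, 3L]
    v <- bilinear_sample(scene$albedo, p[, 1L] / w, p[, 2L] / w, fill = 0)
    if (!is.null(vig)) v <- v * vig
    if (noise_sd > 0) v <- v + rng$rnorm(length(v), 0, noise_sd)
    img <- matrix(as.integer(round(clamp(v, 0, 1) * 255)), fh, fw)
    frames[[i]] <- list(image = img, t = frame_t[i], index = i - 1L)
  }

  # render lines: local (0, y) -> scene via line_H, spectral expansion
  s_prof <- spectral_profile()
  lines_arr <- array(0, dim = c(n_lines, fh, 100L))
  ly <- seq_len(fh) - 1
  for (j in seq_len(n_lines)) {
    p <- hg_apply(line_H[[j]], cbind(0, ly))
    a <- bilinear_sample(scene$albedo, p[, 1L], p[, 2L], fill = 0)
    spec <- outer(a, s_prof)
    if (noise_sd > 0) {
      spec <- spec + matrix(rng$rnorm(length(spec), 0, noise_sd), fh, 100L)
    }
    lines_arr[j, , ] <- spec
  }

  gt <- structure(
    list(frame_H = frame_H, frame_t = frame_t,
         line_H = line_H, line_t = line_t, line_t_true = line_t_true,
         delta_ms = delay_ms, calibration = calibration,
         mm_per_px = scene$mm_per_px,
         scene_size = c(width = sw, height = sh)),
    class = "hsistitch_ground_truth"
  )
  structure(
    list(frames = frames, lines = list(data = lines_arr, t = line_t),
         gt = gt, rgb_fps = rgb_fps, hsi_fps = hsi_fps,
         calibration = calibration, seed = as.integer(seed)),
    class = "hsistitch_scan"
  )
}

#' @export
print.hsistitch_scan <- function(x, ...) {
  cat(sprintf(
    "<hsistitch_scan> %d frames @ %g fps, %d lines @ %g fps, delta=%g ms\n",
    length(x$frames), x$rgb_fps, dim(x$lines$data)[1L], x$hsi_fps,
    x$gt$delta_ms))
  invisible(x)
}

# ground-truth line -> scene homography reconstructed from the frame-pose
# interpolation at an arbitrary corrected timestamp (consistency oracle)
gt_line_placement <- function(gt, trajectory, t_corrected, rgb_fps = 10) {
  u <- t_corrected / (1000 / rgb_fps)
  Hf <- pose_homography(interp_pose(trajectory, u))
  Hf %*% gt$calibration$H_sens %*% gt$calibration$H_pos
}
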