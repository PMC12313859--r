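#' Camera trajectories for the synthetic scanner
#'
#' A trajectory is an ordered table of camera poses, one per RGB frame time.
#' Each pose places the 960x540 camera view on the scene plane through an
#' in-plane translation of the view center (scene px), a rotation (degrees),
#' an isotropic scale factor, and two perspective-tilt parameters (the
#' bottom-row entries of the pose homography). Poses are linearly
#' interpolable to any timestamp between frame times, which is exactly the
#' assumption the stitching stage's homography interpolation makes.
#'
#' Kinds mirror the scan paths used to probe robustness: `translation` is a
#' constant-velocity horizontal sweep; `rotation`, `scale` and `perspective`
#' add one oscillating transform family on top of the sweep; `freehand`
#' combines all of them with smooth pseudo-random phases; `stationary` holds
#' one pose (useful for no-motion tests).
#'
#' @param kind one of `"stationary"`, `"translation"`, `"rotation"`,
#'   `"scale"`, `"perspective"`, `"freehand"`.
#' @param n_frames number of RGB frame poses.
#' @param speed in-plane speed in scene px per frame interval.
#' @param start_x,start_y scene coordinates of the view center at frame 0.
#' @param seed integer seed for the freehand phases.
#' @return object of class `hsistitch_trajectory`: list with `poses` (data
#'   frame: `frame`, `tx`, `ty`, `rot_deg`, `scale`, `px`, `py`), `kind`,
#'   `speed`.
#' @export
make_trajectory <- function(kind = c("translation", "rotation", "scale",
                                     "perspective", "freehand",
                                     "stationary"),
                            n_frames, speed = 1,
                            start_x = 520, start_y = 600, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 1L)
  i <- seq_len(n_frames) - 1L
  tx <- start_x + if (kind == "stationary") 0 else speed * i
  ty <- rep(start_y, n_frames)
  rot <- rep(0, n_frames)
  sc <- rep(1, n_frames)
  px <- rep(0, n_frames)
  py <- rep(0, n_frames)
  ph <- i / max(1L, n_frames - 1L) * 2 * pi
  if (kind == "rotation") rot <- 5 * sin(ph)
  if (kind == "scale") sc <- 1 + 0.06 * sin(ph)
  if (kind == "perspective") {
    px <- 3e-5 * sin(ph)
    py <- 2e-5 * cos(ph)
  }
  if (kind == "freehand") {
    rng <- local_rng(seed)
    phase <- rng$runif(4L, 0, 2 * pi)
    ty <- ty + 12 * sin(ph * 1.3 + phase[1L])
    rot <- 3.5 * sin(ph * 0.9 + phase[2L])
    sc <- 1 + 0.04 * sin(ph * 0.7 + phase[3L])
    px <- 1.5e-5 * sin(ph + phase[4L])
    py <- 1e-5 * cos(ph + phase[2L])
  }
  structure(
    list(
      poses = data.frame(frame = i, tx = tx, ty = ty, rot_deg = rot,
                         scale = sc, px = px, py = py),
      kind = kind, speed = speed
    ),
    class = "hsistitch_trajectory"
  )
}

# frame -> scene homography for one pose row; frame coordinates have their
# origin at the upper-left pixel center, the pose translation places the
# view center
pose_homography <- function(pose, frame_w = 960L, frame_h = 540L) {
  cx <- (frame_w - 1) / 2
  cy <- (frame_h - 1) / 2
  th <- pose$rot_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0,
                sin(th), cos(th), 0,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  S <- diag(c(pose$scale, pose$scale, 1))
  P <- matrix(c(1, 0, 0,
                0, 1, 0,
                pose$px, pose$py, 1), 3L, 3L, byrow = TRUE)
  hg_normalize(hg_translation(pose$tx, pose$ty) %*% R %*% S %*% P %*%
                 hg_translation(-cx, -cy))
}

# pose linearly interpolated at fractional frame index u (clamped to the
# trajectory's ends)
interp_pose <- function(traj, u) {
  p <- traj$poses
  n <- nrow(p)
  u <- min(max(u, 0), n - 1)
  i0 <- floor(u)
  f <- u - i0
  a <- p[i0 + 1L, ]
  b <- p[min(i0 + 2L, n), ]
  out <- a
  for (col in c("tx", "ty", "rot_deg", "scale", "px", "py")) {
    out[[col]] <- (1 - f) * a[[col]] + f * b[[col]]
  }
  out
}
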