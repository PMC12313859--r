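#' Calibration bundle for the dual-sensor scanner
#'
#' Groups everything the pipeline needs to relate the two sensors and the
#' lens: radial distortion coefficients with pinhole intrinsics (enough to
#' build a per-pixel undistortion map for the 960x540 RGB stream), the
#' sensor-alignment homography `H_sens` (RGB and spectrograph image planes
#' are mounted at a slight angle to each other), the slit-position
#' homography `H_pos` (the one-pixel-wide slit line sits at the center
#' column of the RGB view, not at its left edge), and the inter-stream
#' timestamp delay `delta` in milliseconds (about 35 ms between the raw
#' RGB and spectral streams). `H_sens` and `H_pos` are inputs from an
#' offline calibration procedure, never estimated here.
#'
#' @param k1,k2 radial distortion coefficients (zero means no distortion).
#' @param fx,fy,cx,cy pinhole intrinsics in pixels.
#' @param H_sens 3x3 invertible sensor-alignment homography (HSI plane
#'   coordinates to RGB plane coordinates).
#' @param H_pos 3x3 invertible slit-position homography (line-local
#'   coordinates to RGB frame coordinates); default translates the line to
#'   the center column, x = 480.
#' @param delta_ms inter-stream delay in ms (non-negative).
#' @param vignette optional vignetting strength in `[0, 1)` applied by the
#'   simulator (brightness fall-off toward the periphery); 0 disables it.
#' @return object of class `hsistitch_calibration`.
#' @export
calibration_bundle <- function(k1 = 0, k2 = 0,
                               fx = 800, fy = 800, cx = 479.5, cy = 269.5,
                               H_sens = hg_identity(),
                               H_pos = hg_translation(480, 0),
                               delta_ms = 35, vignette = 0) {
  if (!hg_is_invertible(H_sens)) stop("H_sens must be invertible")
  if (!hg_is_invertible(H_pos)) stop("H_pos must be invertible")
  if (delta_ms < 0) stop("delta_ms must be non-negative")
  structure(
    list(k1 = k1, k2 = k2, fx = fx, fy = fy, cx = cx, cy = cy,
         H_sens = H_sens, H_pos = H_pos, delta_ms = delta_ms,
         vignette = vignette),
    class = "hsistitch_calibration"
  )
}

# forward radial distortion: ideal pixel coords -> distorted pixel coords
distort_points <- function(cal, x, y) {
  if (cal$k1 == 0 && cal$k2 == 0) return(list(x = x, y = y))
  nx <- (x - cal$cx) / cal$fx
  ny <- (y - cal$cy) / cal$fy
  r2 <- nx^2 + ny^2
  f <- 1 + cal$k1 * r2 + cal$k2 * r2^2
  list(x = nx * f * cal$fx + cal$cx, y = ny * f * cal$fy + cal$cy)
}

# inverse radial distortion by fixed-point iteration (used only by the
# simulator to render raw distorted frames)
undistort_points <- function(cal, x, y, iterations = 12L) {
  if (cal$k1 == 0 && cal$k2 == 0) return(list(x = x, y = y))
  ndx <- (x - cal$cx) / cal$fx
  ndy <- (y - cal$cy) / cal$fy
  nx <- ndx; ny <- ndy
  for (i in seq_len(iterations)) {
    r2 <- nx^2 + ny^2
    f <- 1 + cal$k1 * r2 + cal$k2 * r2^2
    nx <- ndx / f
    ny <- ndy / f
  }
  list(x = nx * cal$fx + cal$cx, y = ny * cal$fy + cal$cy)
}

#' Build the per-pixel undistortion map
#'
#' Precomputed once per calibration: for every undistorted output pixel the
#' map stores the source coordinates in the raw (distorted) frame. Applying
#' it is then a pure lookup with bilinear interpolation per frame. With zero
#' distortion coefficients the map is the identity.
#'
#' @param calibration a [calibration_bundle()].
#' @param width,height output frame size in pixels.
#' @return object of class `hsistitch_undist_map`: list of matrices `x`, `y`
#'   (height x width source coordinates).
#' @export
build_undistortion_map <- function(calibration, width = 960L,
                                   height = 540L) {
  stopifnot(inherits(calibration, "hsistitch_calibration"))
  xs <- rep(seq_len(width) - 1, each = height)
  ys <- rep(seq_len(height) - 1, times = width)
  d <- distort_points(calibration, xs, ys)
  if (any(!is.finite(d$x)) || any(!is.finite(d$y))) {
    stop("calibration error: distortion model is not invertible over the frame")
  }
  structure(
    list(x = matrix(d$x, height, width), y = matrix(d$y, height, width),
         width = as.integer(width), height = as.integer(height)),
    class = "hsistitch_undist_map"
  )
}

#' Undistort a frame using a precomputed map
#'
#' @param img `[h, w]` matrix or `[h, w, 3]` array of intensities.
#' @param map a map from [build_undistortion_map()].
#' @return image of the same shape, bilinearly resampled.
#' @export
apply_undistortion <- function(img, map) {
  stopifnot(inherits(map, "hsistitch_undist_map"))
  warp1 <- function(m) {
    matrix(bilinear_sample(m, as.vector(map$x), as.vector(map$y)),
           map$height, map$width)
  }
  if (is.matrix(img)) return(warp1(img))
  out <- img
  for (c in seq_len(dim(img)[3L])) out[, , c] <- warp1(img[, , c])
  out
}

# serialize calibration to a plain list (YAML/JSON friendly)
calibration_to_list <- function(cal) {
  list(k1 = cal$k1, k2 = cal$k2, fx = cal$fx, fy = cal$fy,
       cx = cal$cx, cy = cal$cy,
       H_sens = as.vector(t(cal$H_sens)),
       H_pos = as.vector(t(cal$H_pos)),
       delta_ms = cal$delta_ms, vignette = cal$vignette)
}

calibration_from_list <- function(lst) {
  calibration_bundle(
    k1 = lst$k1, k2 = lst$k2, fx = lst$fx, fy = lst$fy,
    cx = lst$cx, cy = lst$cy,
    H_sens = matrix(unlist(lst$H_sens), 3L, 3L, byrow = TRUE),
    H_pos = matrix(unlist(lst$H_pos), 3L, 3L, byrow = TRUE),
    delta_ms = lst$delta_ms,
    vignette = if (is.null(lst$vignette)) 0 else lst$vignette
  )
}
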