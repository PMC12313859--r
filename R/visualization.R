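#' Render the panorama as an overlay on the current RGB frame
#'
#' The panorama keeps the orientation of the first stitched line, so before
#' blending it is warped into the current camera view with the inverse of
#' the most recent final stitching homography, cropped to the 960x540
#' monitor view, and combined with the frame by a linear blend:
#' `alpha * panorama + (1 - alpha) * frame` on occupied pixels; pixels
#' without panorama content show the RGB frame unchanged. A singular
#' homography skips the overlay and passes the frame through.
#'
#' @param frame a `TimedFrame` (or plain image matrix/array, 8-bit).
#' @param state a `hsistitch_panorama`.
#' @param latest_final_H the most recent final (canvas-space) line
#'   homography; defaults to `state$H_offset %*% state$last_H_prime`.
#' @param alpha blend weight in `[0, 1]` (default 0.5).
#' @param calibration the [calibration_bundle()] used while stitching.
#' @return list of class `hsistitch_overlay`: `image` ([540, 960, 3] 8-bit
#'   array), `alpha`, `occupied` (logical matrix of blended pixels).
#' @export
render_overlay <- function(frame, state, latest_final_H = NULL,
                           alpha = 0.5, calibration = calibration_bundle()) {
  img <- if (is.list(frame)) frame$image else frame
  rgb <- if (is.matrix(img)) {
    array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
  } else img
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  passthrough <- function() {
    structure(list(image = rgb, alpha = alpha,
                   occupied = matrix(FALSE, h, w)),
              class = "hsistitch_overlay")
  }
  if (is.null(state$mask) || is.null(state$last_H_prime)) return(passthrough())
  if (is.null(latest_final_H)) {
    latest_final_H <- state$H_offset %*% state$last_H_prime
  }
  if (!hg_is_invertible(latest_final_H)) {
    warning("overlay skipped: singular homography")
    return(passthrough())
  }
  # frame coords -> canvas coords: the frame plane is carried to the line
  # plane by (H_sens H_pos)^-1, then by the final stitching homography
  M <- latest_final_H %*% solve(calibration$H_sens %*% calibration$H_pos)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  src <- hg_apply(M, cbind(xs, ys))
  occ <- matrix(nearest_sample(state$mask * 1, src[, 1L], src[, 2L]) > 0.5,
                h, w)
  out <- rgb
  for (c in 1:3) {
    pano <- matrix(nearest_sample(state$canvas[, , c], src[, 1L],
                                  src[, 2L]), h, w) * 255
    ch <- rgb[, , c]
    ch[occ] <- alpha * pano[occ] + (1 - alpha) * ch[occ]
    out[, , c] <- round(ch)
  }
  structure(list(image = out, alpha = alpha, occupied = occ),
            class = "hsistitch_overlay")
}

#' Display-mode selection
#'
#' Returns a renderer closure for the requested display mode: `"rgb"`
#' passes frames through byte-identically, `"static_hsi"` renders a
#' supplied hypercube snapshot unwarped, `"freehand_hsi"` runs the
#' stitching overlay.
#'
#' @param mode one of `"rgb"`, `"static_hsi"`, `"freehand_hsi"`.
#' @return a function `(frame, state = NULL, snapshot = NULL, ...)`
#'   returning a `hsistitch_overlay`.
#' @export
select_mode <- function(mode = c("rgb", "static_hsi", "freehand_hsi")) {
  if (!is.character(mode) || !mode[1L] %in%
      c("rgb", "static_hsi", "freehand_hsi")) {
    stop("configuration error: unknown display mode")
  }
  mode <- match.arg(mode)
  switch(mode,
    rgb = function(frame, state = NULL, snapshot = NULL, ...) {
      img <- if (is.list(frame)) frame$image else frame
      rgb <- if (is.matrix(img)) {
        array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
      } else img
      structure(list(image = rgb, alpha = 0,
                     occupied = matrix(FALSE, dim(rgb)[1L], dim(rgb)[2L])),
                class = "hsistitch_overlay")
    },
    static_hsi = function(frame, state = NULL, snapshot = NULL, ...) {
      if (is.null(snapshot)) stop("static_hsi mode needs a snapshot")
      structure(list(image = snapshot, alpha = 1,
                     occupied = matrix(TRUE, dim(snapshot)[1L],
                                       dim(snapshot)[2L])),
                class = "hsistitch_overlay")
    },
    freehand_hsi = function(frame, state = NULL, snapshot = NULL, ...) {
      if (is.null(state)) stop("freehand_hsi mode needs a panorama state")
      render_overlay(frame, state, ...)
    }
  )
}
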