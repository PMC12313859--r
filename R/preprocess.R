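#' Contrast-limited adaptive histogram equalization
#'
#' Applied to every incoming RGB frame (clip limit 2.0, 8x8 tile grid by
#' default) to even out illumination before keypoint detection. Operates on
#' the luminance channel; for color input the channels are scaled
#' proportionally to the luminance change so hue is preserved.
#'
#' @param frame `[h, w]` matrix or `[h, w, 3]` array of 8-bit intensities
#'   (0-255).
#' @param clip_limit positive contrast limit.
#' @param tile_grid number of tiles along each axis.
#' @return image of the same shape, 8-bit intensities.
#' @export
apply_clahe <- function(frame, clip_limit = 2.0, tile_grid = 8L) {
  if (clip_limit <= 0) stop("configuration error: clip_limit must be positive")
  gray <- as_gray(frame) / 255
  rng <- diff(range(gray))
  if (rng < 1 / 255) return(frame)  # flat image: nothing to equalize
  # the tiled equalizer needs dimensions divisible by the grid: pad by
  # edge replication and crop back
  h <- nrow(gray); w <- ncol(gray)
  ph <- (tile_grid - h %% tile_grid) %% tile_grid
  pw <- (tile_grid - w %% tile_grid) %% tile_grid
  padded <- gray
  if (ph > 0) padded <- rbind(padded, padded[rep(h, ph), , drop = FALSE])
  if (pw > 0) padded <- cbind(padded, padded[, rep(w, pw), drop = FALSE])
  # EBImage uses [x, y] layout
  eq <- t(EBImage::clahe(t(padded), nx = tile_grid, ny = tile_grid,
                         limit = clip_limit, keep.range = TRUE))
  eq <- clamp(eq[seq_len(h), seq_len(w)], 0, 1)
  if (is.matrix(frame)) {
    return(matrix(as.integer(round(eq * 255)), nrow(frame), ncol(frame)))
  }
  ratio <- eq / pmax(gray, 1 / 255)
  out <- frame
  for (c in 1:3) {
    out[, , c] <- as.integer(round(clamp(frame[, , c] * ratio, 0, 255)))
  }
  out
}

# strict monotone timestamp check shared by both streams
check_monotone <- function(t, what) {
  if (anyNA(t)) stop(sprintf("ingestion error: missing timestamp in %s", what))
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf(
      "ingestion error: non-increasing timestamp in %s at record %d (t = %s)",
      what, bad[1L] + 1L, t[bad[1L] + 1L]))
  }
  invisible(TRUE)
}

#' Ingest and preprocess a scan
#'
#' Turns a simulated scan (or a recording directory, see [read_scan()]) into
#' the two asynchronous streams the pipeline consumes: RGB frames are
#' undistorted through the precomputed calibration map and then
#' CLAHE-equalized; spectral lines pass through untouched. Records are
#' re-emitted in timestamp order and both streams are checked for strictly
#' increasing timestamps. Preprocessing is stateless per record, so
#' re-running on the same input reproduces bit-identical streams. No
#' cross-stream synchronization happens here — that is the stitching
#' stage's job.
#'
#' @param source a `hsistitch_scan` or a directory path readable by
#'   [read_scan()].
#' @param calibration optional [calibration_bundle()] overriding the scan's.
#' @param clip_limit,tile_grid CLAHE parameters.
#' @return list with `frames` (list of preprocessed `TimedFrame`s), `lines`
#'   (unchanged line stack and timestamps), `calibration`.
#' @export
ingest <- function(source, calibration = NULL, clip_limit = 2.0,
                   tile_grid = 8L) {
  if (is.character(source)) source <- read_scan(source)
  stopifnot(inherits(source, "hsistitch_scan"))
  cal <- if (is.null(calibration)) source$calibration else calibration
  frames <- source$frames
  ft <- vapply(frames, function(f) as.numeric(f$t), numeric(1L))
  ord <- order(ft)
  frames <- frames[ord]
  ft <- ft[ord]
  check_monotone(ft, "RGB frames")
  lt <- source$lines$t
  lord <- order(lt)
  check_monotone(lt[lord], "HSI lines")
  lines <- list(data = source$lines$data[lord, , , drop = FALSE],
                t = lt[lord])

  map <- build_undistortion_map(cal, 960L, 540L)
  identity_map <- (cal$k1 == 0 && cal$k2 == 0)
  out_frames <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    img <- frames[[i]]$image
    if (!identity_map) img <- round(apply_undistortion(img, map))
    img <- apply_clahe(img, clip_limit, tile_grid)
    out_frames[[i]] <- list(image = img, t = frames[[i]]$t,
                            index = i - 1L)
  }
  list(frames = out_frames, lines = lines, calibration = cal)
}
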