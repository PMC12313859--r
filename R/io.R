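#' Write a simulated scan to disk
#'
#' On-disk layout: `frames/%06d.png` (8-bit grayscale), `lines.tiff`
#' (one 540 x 100 float page per line), `timestamps.json`,
#' `ground_truth.json` (per-timestamp homographies), `calibration.yaml`.
#'
#' @param scan a [simulate_scan()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "hsistitch_scan"))
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  for (f in scan$frames) {
    png::writePNG(f$image / 255,
                  file.path(dir, "frames",
                            sprintf("%06d.png", f$index)))
  }
  nl <- dim(scan$lines$data)[1L]
  pages <- lapply(seq_len(nl), function(j) {
    clamp(scan$lines$data[j, , ], 0, 1)
  })
  tiff::writeTIFF(pages, file.path(dir, "lines.tiff"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(frames = vapply(scan$frames, `[[`, numeric(1L), "t"),
         lines = scan$lines$t,
         rgb_fps = scan$rgb_fps, hsi_fps = scan$hsi_fps),
    file.path(dir, "timestamps.json"), auto_unbox = TRUE, digits = NA)
  gt <- scan$gt
  jsonlite::write_json(
    list(frame_t = gt$frame_t,
         frame_H = lapply(gt$frame_H, function(h) as.vector(t(h))),
         line_t = gt$line_t, line_t_true = gt$line_t_true,
         line_H = lapply(gt$line_H, function(h) as.vector(t(h))),
         delta_ms = gt$delta_ms, mm_per_px = gt$mm_per_px,
         scene_size = as.list(gt$scene_size)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(calibration_to_list(scan$calibration),
                   file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' Read a scan directory
#'
#' Accepts the [write_scan()] layout, or any directory with
#' `frames/*.png`, `lines.tiff`, `timestamps.json` and `calibration.yaml`
#' (ground truth optional).
#'
#' @param dir directory path.
#' @return a `hsistitch_scan`.
#' @export
read_scan <- function(dir) {
  ts <- jsonlite::read_json(file.path(dir, "timestamps.json"),
                            simplifyVector = TRUE)
  files <- sort(list.files(file.path(dir, "frames"),
                           pattern = "\\.(png|tiff?)$", full.names = TRUE))
  if (length(files) != length(ts$frames)) {
    stop("ingestion error: ", length(files), " frame files but ",
         length(ts$frames), " frame timestamps")
  }
  frames <- lapply(seq_along(files), function(i) {
    img <- if (grepl("png$", files[i])) png::readPNG(files[i])
      else tiff::readTIFF(files[i])
    if (length(dim(img)) == 3L) img <- as_gray(img)
    list(image = matrix(as.integer(round(img * 255)), nrow(img),
                        ncol(img)),
         t = ts$frames[i], index = i - 1L)
  })
  pages <- tiff::readTIFF(file.path(dir, "lines.tiff"), all = TRUE)
  nl <- length(pages)
  if (nl != length(ts$lines)) {
    stop("ingestion error: ", nl, " line pages but ", length(ts$lines),
         " line timestamps")
  }
  arr <- array(0, dim = c(nl, nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (j in seq_len(nl)) arr[j, , ] <- pages[[j]]
  cal <- calibration_from_list(
    yaml::read_yaml(file.path(dir, "calibration.yaml")))
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf)) {
    g <- jsonlite::read_json(gtf, simplifyVector = FALSE)
    to_H <- function(v) matrix(unlist(v), 3L, 3L, byrow = TRUE)
    gt <- structure(
      list(frame_H = lapply(g$frame_H, to_H),
           frame_t = unlist(g$frame_t),
           line_H = lapply(g$line_H, to_H),
           line_t = unlist(g$line_t),
           line_t_true = unlist(g$line_t_true),
           delta_ms = g$delta_ms, calibration = cal,
           mm_per_px = g$mm_per_px,
           scene_size = unlist(g$scene_size)),
      class = "hsistitch_ground_truth")
  }
  structure(
    list(frames = frames, lines = list(data = arr, t = unlist(ts$lines)),
         gt = gt, rgb_fps = ts$rgb_fps, hsi_fps = ts$hsi_fps,
         calibration = cal, seed = NA_integer_),
    class = "hsistitch_scan")
}

#' Write a stitch result to disk
#'
#' Writes `panorama.png`, `mask.png` and `homographies.json` (per-frame
#' verdicts and per-line homographies).
#'
#' @param result a [stitch_scan()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- result$panorama
  if (!is.null(st$canvas)) {
    png::writePNG(clamp(st$canvas, 0, 1), file.path(dir, "panorama.png"))
    png::writePNG(st$mask * 1, file.path(dir, "mask.png"))
  }
  jsonlite::write_json(
    list(frame_log = result$frame_log, line_log = result$line_log,
         n_resets = result$n_resets,
         H_offset = as.vector(t(st$H_offset))),
    file.path(dir, "homographies.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}
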