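#' Keypoint extraction
#'
#' Salient-corner extraction in the spirit of ORB: a Harris corner response
#' computed on the smoothed luminance image, 3x3 non-maximum suppression
#' with subpixel refinement by quadratic fit, the strongest `max_keypoints`
#' responses kept (1000 by default), and a 256-bit BRIEF-style binary
#' descriptor built from pairwise intensity comparisons on a Gaussian-
#' smoothed patch. Coordinates are in pixels with the origin at the frame's
#' upper-left corner. Extraction is deterministic per frame: the comparison
#' pattern is a fixed package constant.
#'
#' @param frame a `TimedFrame` (list with `image`) or a plain image matrix /
#'   array of 8-bit intensities.
#' @param max_keypoints maximum number of keypoints to keep.
#' @param quality_level minimum response as a fraction of the strongest.
#' @return object of class `hsistitch_keypoints`: list with `xy` (n x 2
#'   matrix), `response` (numeric), `desc` (n x 256 0/1 integer matrix).
#' @export
extract_keypoints <- function(frame, max_keypoints = 1000L,
                              quality_level = 0.005) {
  img <- if (is.list(frame)) frame$image else frame
  gray <- as_gray(img) / 255
  h <- nrow(gray); w <- ncol(gray)

  sm <- gauss_blur(gray, 1.2)
  ix <- (shift_matrix(sm, -1L, 0L) - shift_matrix(sm, 1L, 0L)) / 2
  iy <- (shift_matrix(sm, 0L, -1L) - shift_matrix(sm, 0L, 1L)) / 2
  sxx <- gauss_blur(ix * ix, 1.8)
  syy <- gauss_blur(iy * iy, 1.8)
  sxy <- gauss_blur(ix * iy, 1.8)
  detm <- sxx * syy - sxy * sxy
  trc <- sxx + syy
  resp <- detm - 0.04 * trc * trc

  # exclude the border (descriptor patch radius + smoothing support)
  margin <- patch_radius() + 3L
  mask <- matrix(FALSE, h, w)
  mask[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE

  # 3x3 non-maximum suppression by shifted comparisons
  is_max <- mask & resp > 0
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      is_max <- is_max & resp >= shift_matrix(resp, dx, dy)
    }
  }
  idx <- which(is_max)
  if (length(idx) == 0L) {
    return(empty_keypoints())
  }
  r <- resp[idx]
  keep <- r >= quality_level * max(r)
  idx <- idx[keep]; r <- r[keep]
  if (length(idx) > max_keypoints) {
    ord <- order(r, decreasing = TRUE)[seq_len(max_keypoints)]
    idx <- idx[ord]; r <- r[ord]
  } else {
    ord <- order(r, decreasing = TRUE)
    idx <- idx[ord]; r <- r[ord]
  }
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  x <- col - 1L
  y <- row - 1L

  # subpixel refinement: 1-D quadratic fit along each axis
  cpos <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    off <- ifelse(abs(den) > 1e-12, 0.5 * (vm1 - vp1) / den, 0)
    clamp(off, -0.5, 0.5)
  }
  rx <- cpos(resp[cbind(row, col - 1L)], resp[cbind(row, col)],
             resp[cbind(row, col + 1L)])
  ry <- cpos(resp[cbind(row - 1L, col)], resp[cbind(row, col)],
             resp[cbind(row + 1L, col)])
  xy <- cbind(x = x + rx, y = y + ry)

  desc <- brief_descriptors(gauss_blur(gray, 2), x, y)
  structure(list(xy = xy, response = r, desc = desc),
            class = "hsistitch_keypoints")
}

empty_keypoints <- function() {
  structure(list(xy = matrix(numeric(0), 0L, 2L,
                             dimnames = list(NULL, c("x", "y"))),
                 response = numeric(0),
                 desc = matrix(0L, 0L, 256L)),
            class = "hsistitch_keypoints")
}

#' @export
print.hsistitch_keypoints <- function(x, ...) {
  cat(sprintf("<hsistitch_keypoints> %d keypoints\n", nrow(x$xy)))
  invisible(x)
}

n_keypoints <- function(kp) nrow(kp$xy)

patch_radius <- function() 13L

# the fixed BRIEF comparison pattern: 256 offset pairs drawn once from an
# isotropic Gaussian clipped to the patch, deterministic across sessions
brief_pattern <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rng <- local_rng(987654L)
      r <- patch_radius()
      p <- matrix(round(clamp(rng$rnorm(256L * 4L, 0, r / 2.2), -r, r)),
                  256L, 4L)
      colnames(p) <- c("ax", "ay", "bx", "by")
      # avoid degenerate identical pairs
      same <- p[, "ax"] == p[, "bx"] & p[, "ay"] == p[, "by"]
      p[same, "bx"] <- p[same, "bx"] + 1L
      cache <<- p
    }
    cache
  }
})

# 256-bit binary descriptors for keypoints at integer positions (x, y),
# vectorized over keypoints: bit k is [I(p + a_k) > I(p + b_k)]
brief_descriptors <- function(smoothed, x, y) {
  p <- brief_pattern()
  h <- nrow(smoothed)
  n <- length(x)
  # linear indices: column-major [y + 1 + x * h]
  ia <- outer(y, p[, "ay"], "+") + 1L + outer(x, p[, "ax"], "+") * h
  ib <- outer(y, p[, "by"], "+") + 1L + outer(x, p[, "bx"], "+") * h
  d <- matrix(0L, n, 256L)
  d[smoothed[ia] > smoothed[ib]] <- 1L
  d
}

# pairwise Hamming distances between 0/1 descriptor matrices (na x 256,
# nb x 256) via one BLAS product: d_ij = ra_i + rb_j - 2 a_i . b_j
hamming_matrix <- function(a, b) {
  ra <- rowSums(a)
  rb <- rowSums(b)
  cross <- a %*% t(b)
  outer(ra, rb, "+") - 2 * cross
}

#' Match binary descriptors between two keypoint sets
#'
#' Brute-force matcher under the Hamming norm with Lowe's ratio refinement:
#' for every keypoint of `current` the nearest and second-nearest
#' descriptors in `reference` are found, and the match is kept only if
#' `best < ratio * second_best` (strict). When the same reference keypoint
#' is claimed by several current keypoints, only the lowest-distance pair
#' survives. With a reference set of a single descriptor the ratio test
#' cannot be formed and the single candidate is kept.
#'
#' @param current,reference `hsistitch_keypoints` sets.
#' @param ratio Lowe's ratio (default 0.8).
#' @return data.frame of class `hsistitch_matches` with columns
#'   `current` and `reference` (1-based indices) and `distance`.
#' @export
match_descriptors <- function(current, reference, ratio = 0.8) {
  nc <- n_keypoints(current); nr <- n_keypoints(reference)
  empty <- data.frame(current = integer(0), reference = integer(0),
                      distance = numeric(0))
  class(empty) <- c("hsistitch_matches", "data.frame")
  if (nc == 0L || nr == 0L) return(empty)
  D <- hamming_matrix(current$desc, reference$desc)
  best_j <- max.col(-D, ties.method = "first")
  best_d <- D[cbind(seq_len(nc), best_j)]
  if (nr >= 2L) {
    D[cbind(seq_len(nc), best_j)] <- Inf
    second_d <- D[cbind(seq_len(nc), max.col(-D, ties.method = "first"))]
    keep <- best_d < ratio * second_d
  } else {
    keep <- rep(TRUE, nc)  # single candidate: ratio test skipped
  }
  m <- data.frame(current = which(keep), reference = best_j[keep],
                  distance = best_d[keep])
  # resolve cross-duplicates: keep the lowest-distance claim per reference
  m <- m[order(m$distance), , drop = FALSE]
  m <- m[!duplicated(m$reference), , drop = FALSE]
  m <- m[order(m$current), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("hsistitch_matches", "data.frame")
  m
}
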