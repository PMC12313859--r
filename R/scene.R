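#' Synthetic planar test scenes
#'
#' The synthetic scanner images a planar, achromatic target — the desk-scale
#' analogue of a resolution test chart or a printed still from laparoscopic
#' surgery. A scene is a 2-D albedo grid in `[0, 1]` plus a physical scale in
#' millimetres per scene pixel (default 85/960, i.e. the scale at which a
#' 960-pixel-wide camera view spans 85 mm).
#'
#' Two kinds are available:
#' \describe{
#'   \item{`"usaf"`}{high-contrast, axis-aligned bar triplets at several
#'     scales on a lightly textured background — sharp corners for keypoint
#'     detectors, plus easily segmentable dark rectangles for geometry
#'     checks.}
#'   \item{`"texture"`}{a smooth multi-scale random field with spatially
#'     varying gradients and no large uniform regions — surgery-like
#'     low-contrast texture that exercises matching without strong edges.}
#' }
#'
#' @param seed integer seed; output is deterministic in `(seed, kind, width,
#'   height)`. The caller's RNG state is untouched.
#' @param kind `"usaf"` or `"texture"`.
#' @param width,height scene size in pixels (each at least 512).
#' @param mm_per_px physical scale.
#' @return object of class `hsistitch_scene`: list with `albedo` (height x
#'   width matrix), `mm_per_px`, `kind`, `seed`.
#' @export
generate_scene <- function(seed, kind = c("usaf", "texture"),
                           width = 2000L, height = 1200L,
                           mm_per_px = 85 / 960) {
  if (!is.character(kind) || !kind[1L] %in% c("usaf", "texture")) {
    stop("unknown scene kind: ", paste(kind[1L], collapse = ""))
  }
  kind <- match.arg(kind)
  stopifnot(width >= 512L, height >= 512L)
  width <- as.integer(width); height <- as.integer(height)
  rng <- local_rng(seed)
  albedo <- switch(kind,
    usaf = scene_usaf(rng, width, height),
    texture = scene_texture(rng, width, height)
  )
  structure(
    list(albedo = albedo, mm_per_px = mm_per_px, kind = kind,
         seed = as.integer(seed)),
    class = "hsistitch_scene"
  )
}

#' @export
print.hsistitch_scene <- function(x, ...) {
  cat(sprintf("<hsistitch_scene> kind=%s %dx%d px, %.4f mm/px, seed=%d\n",
              x$kind, ncol(x$albedo), nrow(x$albedo), x$mm_per_px, x$seed))
  invisible(x)
}

# bilinear upsampling of a coarse random grid to (h, w) — cheap smooth noise
upsample_field <- function(rng, h, w, spacing, amplitude) {
  ch <- ceiling(h / spacing) + 2L
  cw <- ceiling(w / spacing) + 2L
  coarse <- matrix(rng$rnorm(ch * cw), ch, cw)
  xs <- (seq_len(w) - 1) / spacing
  ys <- (seq_len(h) - 1) / spacing
  xg <- rep(xs, each = h)
  yg <- rep(ys, times = w)
  matrix(bilinear_sample(coarse, xg, yg), h, w) * amplitude
}

scene_texture <- function(rng, w, h) {
  # band-limited multi-scale field: a printed target seen through real
  # optics carries no structure below the lens resolution, so the finest
  # scale is ~4 px rather than per-pixel noise
  f <- upsample_field(rng, h, w, 96L, 0.28) +
    upsample_field(rng, h, w, 24L, 0.18) +
    upsample_field(rng, h, w, 6L, 0.12) +
    upsample_field(rng, h, w, 4L, 0.05)
  # gentle global illumination gradient so no region is statistically flat
  gx <- matrix(rep(seq(-0.5, 0.5, length.out = w), each = h), h, w)
  f <- f + 0.1 * gx
  0.5 + f / max(abs(range(f))) * 0.38
}

scene_usaf <- function(rng, w, h) {
  # textured light background keeps detectors fed between chart elements
  bg <- 0.82 + upsample_field(rng, h, w, 10L, 0.05) +
    matrix(rng$rnorm(h * w), h, w) * 0.015
  img <- clamp(bg, 0.6, 0.95)
  dark <- 0.08
  draw_rect <- function(x0, y0, rw, rh) {
    xa <- max(1, round(x0)); xb <- min(w, round(x0 + rw - 1))
    ya <- max(1, round(y0)); yb <- min(h, round(y0 + rh - 1))
    if (xa <= xb && ya <= yb) img[ya:yb, xa:xb] <<- dark
  }
  # a bar triplet: three parallel bars of width bw, length 5*bw, gap bw
  draw_triplet <- function(x0, y0, bw, vertical) {
    for (k in 0:2) {
      if (vertical) draw_rect(x0 + k * 2 * bw, y0, bw, 5 * bw)
      else draw_rect(x0, y0 + k * 2 * bw, 5 * bw, bw)
    }
  }
  # groups at 4 scales, tiled across the scene like a repeated chart
  bws <- c(36, 20, 10, 5)
  gx <- floor(w / 2.2); gy <- floor(h / 2.2)
  for (ix in 0:1) {
    for (iy in 0:1) {
      ox <- 80 + ix * gx + round(rng$runif(1, -15, 15))
      oy <- 80 + iy * gy + round(rng$runif(1, -15, 15))
      x <- ox
      for (bw in bws) {
        draw_triplet(x, oy, bw, vertical = TRUE)
        draw_triplet(x, oy + 5 * bws[1L] + 40, bw, vertical = FALSE)
        x <- x + 5 * bw + 60
      }
    }
  }
  img
}
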