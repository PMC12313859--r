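# Internal raster helpers. Images are numeric matrices indexed [row, col]
# with pixel (x, y) stored at [y + 1, x + 1]; pixel centers sit at integer
# coordinates, origin at the upper-left corner.

# bilinear sample of matrix `img` at continuous coords (x, y); points
# outside the grid return `fill`
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbor at the last row/col so edge pixels still sample
  x0c <- pmin(pmax(x0, 0), w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1)
  y1c <- pmin(y0c + 1, h - 1)
  i00 <- y0c + 1 + x0c * h
  i10 <- y0c + 1 + x1c * h
  i01 <- y1c + 1 + x0c * h
  i11 <- y1c + 1 + x1c * h
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i10] +
    (1 - fx) * fy * img[i01] + fx * fy * img[i11]
  v[!inside] <- fill
  v
}

# nearest-neighbour sample; outside -> fill
nearest_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(x); yi <- round(y)
  inside <- xi >= 0 & yi >= 0 & xi <= w - 1 & yi <= h - 1
  xi <- pmin(pmax(xi, 0), w - 1)
  yi <- pmin(pmax(yi, 0), h - 1)
  v <- img[yi + 1 + xi * h]
  v[!inside] <- fill
  v
}

# shift matrix by (dx, dy) pixels (content moves right/down for positive
# shifts), zero padding
shift_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  src_r <- max(1, 1 - dy):min(h, h - dy)
  src_c <- max(1, 1 - dx):min(w, w - dx)
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  out
}

# separable Gaussian blur (kernel truncated at 3 sigma) as two sparse
# band-matrix products; edge handled by clamping (replication padding);
# band matrices are cached per (size, sigma)
.blur_cache <- new.env(parent = emptyenv())

blur_band <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  got <- get0(key, .blur_cache)
  if (!is.null(got)) return(got)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  i <- rep(seq_len(n), each = length(k))
  j <- pmin(pmax(i + rep(-r:r, times = n), 1L), n)
  B <- Matrix::sparseMatrix(i = i, j = j, x = rep(k, times = n),
                            dims = c(n, n))
  B <- methods::as(B, "CsparseMatrix")
  assign(key, B, .blur_cache)
  B
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Kv <- blur_band(nrow(img), sigma)
  Kh <- blur_band(ncol(img), sigma)
  as.matrix(Kv %*% img %*% Matrix::t(Kh))
}

# reduce an [h, w] matrix or [h, w, 3] array to luminance matrix
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop("expected an [h, w] matrix or [h, w, 3] array")
}

# clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
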