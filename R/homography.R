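#' Homography utilities
#'
#' A homography is the pipeline's universal currency: a 3x3 projective
#' transform acting on homogeneous pixel coordinates `(x, y, 1)`, with the
#' image origin at the upper-left corner, x growing rightwards and y
#' downwards. All helpers here treat plain 3x3 numeric matrices as
#' homographies; [hg_normalize()] scales a matrix so its bottom-right
#' element is 1, the convention assumed by the element-wise interpolation
#' used during line stitching.
#'
#' @name homography
NULL

#' Normalize a homography to bottom-right element 1
#'
#' @param H 3x3 numeric matrix with nonzero `[3, 3]` element.
#' @return 3x3 matrix equal to `H / H[3, 3]`.
#' @export
hg_normalize <- function(H) {
  stopifnot(is.matrix(H), all(dim(H) == c(3L, 3L)))
  if (abs(H[3L, 3L]) < .Machine$double.eps) {
    stop("homography cannot be normalized: bottom-right element is zero")
  }
  H / H[3L, 3L]
}

#' Identity and translation homographies
#'
#' @param tx,ty translation in pixels.
#' @return 3x3 matrix.
#' @export
hg_identity <- function() diag(3)

#' @rdname hg_identity
#' @export
hg_translation <- function(tx, ty) {
  H <- diag(3)
  H[1L, 3L] <- tx
  H[2L, 3L] <- ty
  H
}

#' Apply a homography to 2-D points
#'
#' @param H 3x3 homography.
#' @param pts numeric matrix with columns x, y (one row per point), or a
#'   length-2 vector for a single point.
#' @return matrix of mapped points, same shape as `pts`.
#' @export
hg_apply <- function(H, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, nrow = 1L)
  stopifnot(ncol(pts) == 2L)
  ph <- cbind(pts, 1) %*% t(H)
  w <- ph[, 3L]
  if (any(abs(w) < 1e-12)) {
    stop("homography maps a point to infinity (zero homogeneous scale)")
  }
  out <- ph[, 1:2, drop = FALSE] / w
  if (single) out[1L, ] else out
}

#' Test invertibility of a homography
#'
#' @param H 3x3 matrix.
#' @param tol reciprocal-condition tolerance.
#' @return logical.
#' @export
hg_is_invertible <- function(H, tol = 1e-12) {
  is.matrix(H) && all(dim(H) == c(3L, 3L)) && all(is.finite(H)) &&
    rcond(H) > tol
}

# Hartley-style normalization of points for stable DLT: translate centroid
# to origin, scale mean distance to sqrt(2).
normalize_points <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  md <- mean(d)
  s <- if (md > 1e-12) sqrt(2) / md else 1
  Tm <- matrix(c(s, 0, -s * ctr[1L],
                 0, s, -s * ctr[2L],
                 0, 0, 1), 3L, 3L, byrow = TRUE)
  list(pts = hg_apply(Tm, pts), T = Tm)
}

#' Fit a homography to point correspondences (direct linear transform)
#'
#' Least-squares DLT with Hartley point normalization. Used both for the
#' minimal 4-point RANSAC hypothesis and for the final refit on all inliers.
#'
#' @param src,dst matrices of corresponding points (columns x, y); `src`
#'   points are mapped onto `dst` points.
#' @return 3x3 homography with `H[3, 3] == 1`, or `NULL` when the
#'   configuration is degenerate (e.g. collinear points).
#' @export
hg_fit <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4L)
  ns <- normalize_points(src)
  nd <- normalize_points(dst)
  s <- ns$pts; d <- nd$pts
  n <- nrow(s)
  A <- matrix(0, 2L * n, 9L)
  i1 <- seq(1L, 2L * n, by = 2L)
  A[i1, 1L] <- s[, 1L]; A[i1, 2L] <- s[, 2L]; A[i1, 3L] <- 1
  A[i1, 7L] <- -d[, 1L] * s[, 1L]
  A[i1, 8L] <- -d[, 1L] * s[, 2L]
  A[i1, 9L] <- -d[, 1L]
  i2 <- i1 + 1L
  A[i2, 4L] <- s[, 1L]; A[i2, 5L] <- s[, 2L]; A[i2, 6L] <- 1
  A[i2, 7L] <- -d[, 2L] * s[, 1L]
  A[i2, 8L] <- -d[, 2L] * s[, 2L]
  A[i2, 9L] <- -d[, 2L]
  sv <- tryCatch(svd(A, nu = 0L, nv = 9L), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  # degenerate configuration: two (near-)zero singular values
  if (sv$d[8L] < 1e-9 * sv$d[1L]) return(NULL)
  h <- sv$v[, 9L]
  Hn <- matrix(h, 3L, 3L, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3L, 3L]) < 1e-12) return(NULL)
  H <- hg_normalize(H)
  if (!all(is.finite(H))) return(NULL)
  H
}

# squared reprojection error of src -> dst under H, vectorized
reproj_errors <- function(H, src, dst) {
  ph <- cbind(src, 1) %*% t(H)
  w <- ph[, 3L]
  bad <- abs(w) < 1e-12
  w[bad] <- 1
  dx <- ph[, 1L] / w - dst[, 1L]
  dy <- ph[, 2L] / w - dst[, 2L]
  e <- sqrt(dx^2 + dy^2)
  e[bad] <- Inf
  e
}

#' Robust homography estimation with RANSAC
#'
#' Seeded 4-point RANSAC with adaptive iteration count followed by a
#' least-squares refit on the consensus set. Defaults follow the pipeline's
#' registration settings: confidence 0.995 and an inlier reprojection
#' threshold of 8.0 pixels.
#'
#' @param src,dst corresponding points (columns x, y); the estimate maps
#'   `src` onto `dst`.
#' @param confidence target probability of drawing at least one outlier-free
#'   minimal sample.
#' @param threshold inlier reprojection threshold in pixels.
#' @param seed integer seed for the sampler (local RNG; the caller's random
#'   state is untouched).
#' @param max_iter hard cap on RANSAC iterations.
#' @return list with `H` (3x3 or `NULL` on failure), `inliers` (logical
#'   vector), `n_inliers`.
#' @export
hg_ransac <- function(src, dst, confidence = 0.995, threshold = 8.0,
                      seed = 0L, max_iter = 2000L) {
  stopifnot(nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 4L) {
    return(list(H = NULL, inliers = logical(n), n_inliers = 0L))
  }
  rng <- local_rng(seed)
  best_in <- logical(n)
  best_cnt <- 0L
  best_H <- NULL
  it <- 0L
  needed <- max_iter
  while (it < min(needed, max_iter)) {
    it <- it + 1L
    idx <- rng$sample_int(n, 4L)
    H <- hg_fit(src[idx, , drop = FALSE], dst[idx, , drop = FALSE])
    if (is.null(H)) next
    e <- reproj_errors(H, src, dst)
    inl <- e <= threshold
    cnt <- sum(inl)
    if (cnt > best_cnt) {
      best_cnt <- cnt
      best_in <- inl
      best_H <- H
      w <- cnt / n
      # adaptive stopping criterion
      p_good <- w^4
      needed <- if (p_good >= 1 - 1e-12) it else {
        ceiling(log(1 - confidence) / log(1 - p_good))
      }
    }
  }
  if (is.null(best_H) || best_cnt < 4L) {
    return(list(H = NULL, inliers = logical(n), n_inliers = 0L))
  }
  # refit on consensus set, then re-evaluate inliers once
  H <- hg_fit(src[best_in, , drop = FALSE], dst[best_in, , drop = FALSE])
  if (is.null(H)) H <- best_H
  e <- reproj_errors(H, src, dst)
  inl <- e <= threshold
  if (sum(inl) >= 4L) {
    H2 <- hg_fit(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    if (!is.null(H2)) {
      e2 <- reproj_errors(H2, src, dst)
      inl2 <- e2 <= threshold
      if (sum(inl2) >= sum(inl)) {
        H <- H2
        inl <- inl2
      }
    }
  }
  list(H = hg_normalize(H), inliers = inl, n_inliers = sum(inl))
}

# Small deterministic RNG facility that never touches .Random.seed:
# saves/restores the global state around a private Mersenne stream.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    old2 <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old2)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old2, globalenv())
      }
    })
    f()
  }
  list(
    sample_int = function(n, k) with_state(function() sample.int(n, k)),
    runif = function(k, min = 0, max = 1) {
      with_state(function() stats::runif(k, min, max))
    },
    rnorm = function(k, mean = 0, sd = 1) {
      with_state(function() stats::rnorm(k, mean, sd))
    }
  )
}
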