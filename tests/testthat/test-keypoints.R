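test_that("keypoint extraction finds nothing on uniform frames and is deterministic", {
  flat <- matrix(128L, 540, 960)
  kp <- extract_keypoints(flat)
  expect_lte(nrow(kp$xy), 5L)

  fr <- fx_frame()
  a <- extract_keypoints(fr)
  b <- extract_keypoints(fr)
  expect_identical(a$xy, b$xy)
  expect_identical(a$desc, b$desc)
  expect_lte(nrow(a$xy), 1000L)
  expect_true(all(a$xy[, 1] >= 0 & a$xy[, 1] < 960))
  expect_true(all(a$xy[, 2] >= 0 & a$xy[, 2] < 540))
  expect_true(all(diff(a$response) <= 1e-12))  # ordered by response
})

test_that("a bar-target frame yields abundant keypoints near bar corners", {
  traj <- make_trajectory("stationary", 2L, start_x = 700, start_y = 500)
  scan <- simulate_scan(fx_scene("usaf", 0L), traj)
  st <- ingest(scan)
  kp <- extract_keypoints(st$frames[[1L]])
  expect_gte(nrow(kp$xy), 100L)
  # keypoints should concentrate near intensity edges of the chart
  img <- st$frames[[1L]]$image
  gx <- abs(img[, c(2:960, 960)] - img)
  gy <- abs(img[c(2:540, 540), ] - img)
  grad <- gx + gy
  near_edge <- vapply(seq_len(nrow(kp$xy)), function(i) {
    x <- round(kp$xy[i, 1]) + 1L
    y <- round(kp$xy[i, 2]) + 1L
    xs <- max(1L, x - 3L):min(960L, x + 3L)
    ys <- max(1L, y - 3L):min(540L, y + 3L)
    max(grad[ys, xs]) > 30
  }, logical(1L))
  expect_gt(mean(near_edge), 0.8)
})

test_that("ratio-test boundaries follow the strict inequality", {
  mk <- function(desc, xy = NULL) {
    n <- nrow(desc)
    if (is.null(xy)) xy <- cbind(seq_len(n) * 10, seq_len(n) * 10)
    structure(list(xy = xy, response = rep(1, n), desc = desc),
              class = "hsistitch_keypoints")
  }
  base <- matrix(0L, 1L, 256L)
  ref10 <- base; ref10[1, 1:10] <- 1L     # distance 10 from base
  ref16 <- base; ref16[1, 1:16] <- 1L     # distance 16
  ref20 <- base; ref20[1, 101:120] <- 1L  # distance 20

  # best 10 vs second 20 at ratio 0.8: 10 < 16 -> kept
  m <- match_descriptors(mk(base), mk(rbind(ref10, ref20)), ratio = 0.8)
  expect_equal(nrow(m), 1L)
  expect_equal(m$distance, 10)
  # best 16 vs second 20: 16 < 0.8 * 20 is false (strict) -> rejected
  m2 <- match_descriptors(mk(base), mk(rbind(ref16, ref20)), ratio = 0.8)
  expect_equal(nrow(m2), 0L)
})

test_that("a set matched against itself self-matches at distance zero", {
  kp <- extract_keypoints(fx_frame(), max_keypoints = 200L)
  m <- match_descriptors(kp, kp, ratio = 0.8)
  expect_gt(nrow(m), 150L)
  expect_true(all(m$distance == 0))
  expect_true(all(m$current == m$reference))
  # one-to-one over surviving pairs
  expect_false(any(duplicated(m$reference)))
})

test_that("single-candidate reference keeps the match (ratio test skipped)", {
  one <- structure(list(xy = cbind(5, 5), response = 1,
                        desc = matrix(0L, 1L, 256L)),
                   class = "hsistitch_keypoints")
  m <- match_descriptors(one, one, ratio = 0.8)
  expect_equal(nrow(m), 1L)
})

test_that("matching consecutive simulated frames recovers the frame-to-frame motion", {
  st <- fx_translation_streams()
  kp2 <- extract_keypoints(st$frames[[2L]])
  kp1 <- extract_keypoints(st$frames[[1L]])
  m <- match_descriptors(kp2, kp1, ratio = 0.8)
  fit <- estimate_homography(m, kp2, kp1, seed = 8L)
  expect_true(fit$ok)
  expect_gte(fit$n_inliers, 40L)
  gt <- fx_translation_scan()$gt
  H_true <- solve(gt$frame_H[[1L]]) %*% gt$frame_H[[2L]]
  grid <- cbind(c(0, 960, 0, 960, 480), c(0, 0, 540, 540, 270))
  err <- sqrt(rowSums((hg_apply(fit$H, grid) - hg_apply(H_true, grid))^2))
  expect_lt(max(err), 0.3)
})
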