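test_that("zero distortion gives the identity undistortion map, deterministically", {
  cal <- calibration_bundle()
  m1 <- build_undistortion_map(cal, 64L, 48L)
  expect_equal(m1$x, matrix(rep(0:63, each = 48), 48, 64))
  expect_equal(m1$y, matrix(rep(0:47, times = 64), 48, 64))
  m2 <- build_undistortion_map(cal, 64L, 48L)
  expect_identical(m1, m2)
})

test_that("a straight edge imaged under barrel distortion is straight after undistortion", {
  # scene with one dark vertical stripe, imaged by a stationary camera
  alb <- matrix(0.9, 900, 1600)
  alb[, 800:820] <- 0.1
  scene <- structure(list(albedo = alb, mm_per_px = 85 / 960,
                          kind = "texture", seed = 0L),
                     class = "hsistitch_scene")
  traj <- make_trajectory("stationary", 2L, start_x = 520, start_y = 460)
  cal <- calibration_bundle(k1 = -0.08)
  scan <- simulate_scan(scene, traj, calibration = cal)

  stripe_center <- function(img) {
    # darkness-weighted centroid per row over the stripe neighbourhood
    cols <- 700:860
    sub <- 255 - img[, cols]
    sub[sub < 100] <- 0
    rows <- which(rowSums(sub) > 0)
    ctr <- (sub[rows, ] %*% (cols - 1)) / rowSums(sub[rows, ])
    data.frame(y = rows - 1, x = as.vector(ctr))
  }
  raw <- stripe_center(scan$frames[[1L]]$image)
  fit_raw <- stats::lm(x ~ y, data = raw)
  expect_gt(max(abs(stats::resid(fit_raw))), 1)  # visibly curved when raw

  und <- apply_undistortion(scan$frames[[1L]]$image,
                            build_undistortion_map(cal))
  cor <- stripe_center(und)
  fit <- stats::lm(x ~ y, data = cor)
  expect_lt(max(abs(stats::resid(fit))), 0.5)
})

test_that("CLAHE preserves flat images and the 8-bit range, and raises local contrast", {
  flat <- matrix(77L, 540, 960)
  out <- apply_clahe(flat)
  expect_lte(max(abs(out - flat)), 1)
  rng <- fx_rng(31L)
  lowc <- matrix(as.integer(round(128 + rng$rnorm(540 * 960, 0, 4))),
                 540, 960)
  eq <- apply_clahe(lowc, clip_limit = 2.0, tile_grid = 8L)
  expect_true(all(eq >= 0 & eq <= 255))
  tile <- function(m) m[203:270, 361:480]  # one interior tile
  expect_gt(stats::sd(tile(eq)), stats::sd(tile(lowc)))
  expect_error(apply_clahe(lowc, clip_limit = 0), "clip_limit")
})

test_that("ingest preserves counts, orders by timestamp, and rejects duplicates", {
  scan <- fx_translation_scan()
  st <- ingest(scan)
  expect_length(st$frames, length(scan$frames))
  expect_equal(dim(st$lines$data), dim(scan$lines$data))

  shuffled <- scan
  perm <- c(3L, 1L, 2L, seq(4L, length(scan$frames)))
  shuffled$frames <- scan$frames[perm]
  st2 <- ingest(shuffled)
  expect_identical(vapply(st2$frames, `[[`, numeric(1), "t"),
                   vapply(st$frames, `[[`, numeric(1), "t"))
  expect_identical(st2$frames[[1L]]$image, st$frames[[1L]]$image)

  dup <- scan
  dup$frames[[2L]]$t <- dup$frames[[1L]]$t
  expect_error(ingest(dup), "non-increasing timestamp")
})

test_that("ingest is stateless: re-running yields bit-identical streams", {
  a <- ingest(fx_translation_scan())
  b <- ingest(fx_translation_scan())
  expect_identical(a$frames[[5L]]$image, b$frames[[5L]]$image)
  expect_identical(a$lines, b$lines)
})
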