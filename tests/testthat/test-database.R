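cfg <- stitch_config()

rand_kp <- function(rng, n, response = NULL) {
  structure(
    list(xy = cbind(rng$runif(n, 20, 940), rng$runif(n, 20, 520)),
         response = if (is.null(response)) rev(seq_len(n)) else response,
         desc = matrix(as.integer(rng$runif(n * 256L) > 0.5), n, 256L)),
    class = "hsistitch_keypoints")
}

test_that("bootstrapped database self-matches at distance zero and yields identity", {
  rng <- fx_rng(1L)
  kp <- rand_kp(rng, 300L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), kp)
  expect_equal(hsistitch:::db_size(db), 300L)
  m <- global_match(kp, db)
  expect_true(all(m$distance == 0))
  fit <- estimate_global(m, kp, db, hg_identity(), cfg, seed = 2L)
  expect_lt(max(abs(fit$H - diag(3))), 1e-6)
  expect_equal(fit$verdict, "ok")
})

test_that("global matching forwards only the 500 best-ranked matches", {
  rng <- fx_rng(2L)
  kp <- rand_kp(rng, 600L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), kp)
  m <- global_match(kp, db, max_matches = 500L)
  expect_equal(nrow(m), 500L)
  expect_error(global_match(kp, keypoint_db()), "reset-required")
})

test_that("a database of unrelated descriptors cannot support registration", {
  rng <- fx_rng(3L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), rand_kp(rng, 400L))
  other <- rand_kp(rng, 400L)
  m <- global_match(other, db)
  fit <- estimate_global(m, other, db, hg_identity(), cfg, seed = 4L)
  expect_true(fit$verdict %in% c("low_inliers", "distorted",
                                 "excessive_motion"))
})

test_that("maintenance adds only the 50 strongest unmatched keypoints, warped", {
  rng <- fx_rng(4L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), rand_kp(rng, 10L))
  fresh <- rand_kp(rng, 60L, response = 60:1)
  no_matches <- data.frame(current = integer(0), reference = integer(0),
                           distance = numeric(0))
  H <- hg_translation(100, 0)
  db2 <- db_maintain(db, fresh, no_matches, logical(0), H, "ok", cfg)
  expect_equal(hsistitch:::db_size(db2), 10L + 50L)
  # the 50 strongest (responses 60..11) were added at warped coordinates
  added <- db2$xy[11:60, ]
  expect_equal(added, hg_apply(H, fresh$xy[1:50, ]), tolerance = 1e-12)
})

test_that("entries are evicted only after exceeding the 80-frame age limit", {
  rng <- fx_rng(5L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), rand_kp(rng, 30L))
  empty_kp <- structure(list(xy = matrix(numeric(0), 0L, 2L),
                             response = numeric(0),
                             desc = matrix(0L, 0L, 256L)),
                        class = "hsistitch_keypoints")
  no_matches <- data.frame(current = integer(0), reference = integer(0),
                           distance = numeric(0))
  for (i in 1:80) {
    db <- db_maintain(db, empty_kp, no_matches, logical(0), hg_identity(),
                      "ok", cfg)
  }
  expect_equal(hsistitch:::db_size(db), 30L)  # age 80: still allowed
  db <- db_maintain(db, empty_kp, no_matches, logical(0), hg_identity(),
                    "ok", cfg)
  expect_equal(hsistitch:::db_size(db), 0L)   # age 81: evicted
})

test_that("inlier matches are updated in place and outliers discarded", {
  rng <- fx_rng(6L)
  base <- rand_kp(rng, 20L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), base)
  db$age <- rep(7L, 20L)
  cur <- rand_kp(rng, 20L)
  matches <- data.frame(current = 1:6, reference = 1:6,
                        distance = c(1, 2, 3, 4, 5, 6))
  inliers <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  H <- hg_translation(10, 20)
  small <- cfg; small$max_updates <- 2L
  db2 <- db_maintain(db, cur, matches, inliers, H, "ok", small)
  # entries 5, 6 (outlier matches) deleted; 4 inliers + 14 untouched + 50 new
  expect_equal(hsistitch:::db_size(db2), 20L - 2L + 14L)
  # the two lowest-distance inliers carry the warped current detection
  expect_equal(db2$xy[1:2, ], hg_apply(H, cur$xy[1:2, ]), tolerance = 1e-12)
  expect_equal(db2$desc[1:2, ], cur$desc[1:2, ])
  # inliers beyond the update cap keep coordinates but are rejuvenated
  expect_equal(db2$xy[3:4, ], base$xy[3:4, ], tolerance = 1e-12)
  expect_equal(db2$age[1:4], rep(0L, 4L))
  # unmatched entries aged by one
  expect_equal(db2$age[5L], 8L)
})

test_that("a discarded frame only deletes the participants of the implausible homography", {
  rng <- fx_rng(7L)
  db <- hsistitch:::db_bootstrap(keypoint_db(), rand_kp(rng, 15L))
  cur <- rand_kp(rng, 15L)
  matches <- data.frame(current = 1:3, reference = c(2L, 5L, 9L),
                        distance = c(1, 2, 3))
  db2 <- db_maintain(db, cur, matches, c(TRUE, FALSE, TRUE),
                     hg_identity(), "distorted", cfg)
  expect_equal(hsistitch:::db_size(db2), 12L)
  expect_equal(db2$age, db$age[-c(2L, 5L, 9L)])  # no ageing either
})

test_that("database size stays bounded over a scan and poisoned entries are excluded", {
  res <- fx_translation_result()
  n_frames <- nrow(res$frame_log)
  expect_lte(hsistitch:::db_size(res$db), 1000L + 50L * n_frames)

  # poison a clean geometric configuration with 70% gross outliers
  rng <- fx_rng(8L)
  n <- 200L
  kp <- rand_kp(rng, n)
  db_xy <- hg_apply(hg_translation(30, -10), kp$xy)
  poisoned <- seq_len(140L)
  db_xy[poisoned, ] <- cbind(rng$runif(140L, 0, 960),
                             rng$runif(140L, 0, 540))
  db <- structure(list(xy = db_xy, desc = kp$desc,
                       age = integer(n), started = TRUE),
                  class = "hsistitch_db")
  m <- data.frame(current = seq_len(n), reference = seq_len(n),
                  distance = numeric(n))
  fit <- estimate_global(m, kp, db, hg_identity(), cfg, seed = 9L)
  expect_equal(fit$verdict, "ok")
  expect_gte(mean(!fit$inliers[poisoned]), 0.95)
})

test_that("global registration drifts less than composed local registration on an out-and-back path", {
  # 26 frames out, 26 back to the start
  n_half <- 26L
  tx <- c(520 + 2 * (0:(n_half - 1L)),
          520 + 2 * ((n_half - 2L):0))
  traj <- fx_custom_trajectory(tx, 460)
  scan <- simulate_scan(fx_scene(), traj, noise_sd = 0.01, seed = 12L)
  st <- ingest(scan)
  gt <- scan$gt
  n <- length(st$frames)
  H_true_last <- solve(gt$frame_H[[1L]]) %*% gt$frame_H[[n]]

  grid <- cbind(c(0, 960, 0, 960, 480), c(0, 0, 540, 540, 270))
  err_vs <- function(H) max(sqrt(rowSums(
    (hg_apply(H, grid) - hg_apply(H_true_last, grid))^2)))

  kp_all <- lapply(st$frames, extract_keypoints)
  H_comp <- hg_identity()
  for (i in 2:n) {
    m <- match_descriptors(kp_all[[i]], kp_all[[i - 1L]], 0.8)
    fit <- estimate_homography(m, kp_all[[i]], kp_all[[i - 1L]], seed = 14L)
    expect_true(fit$ok)
    H_comp <- H_comp %*% fit$H
  }
  db <- hsistitch:::db_bootstrap(keypoint_db(), kp_all[[1L]])
  H_prev <- hg_identity()
  cfg2 <- stitch_config(seed = 13L)
  for (i in 2:n) {
    mg <- global_match(kp_all[[i]], db, cfg2$max_matches)
    fg <- estimate_global(mg, kp_all[[i]], db, H_prev, cfg2, seed = 100L + i)
    if (fg$verdict == "ok") H_prev <- fg$H
    db <- db_maintain(db, kp_all[[i]], mg, fg$inliers, fg$H, fg$verdict,
                      cfg2)
  }
  expect_lt(err_vs(H_prev), err_vs(H_comp))
})
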