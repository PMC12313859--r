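test_that("line selection honours the half-open, delay-corrected membership", {
  buf <- data.frame(j = 1:3, t = c(100, 150, 200))
  sel <- select_lines(buf, 100, 200, delta = 0)
  expect_equal(sel$set$t, c(100, 150))  # t_prev included, t_cur excluded

  # enumeration oracle: lines every 15 ms, delta 35, interval [1000, 1100)
  ts <- seq(960, 1065, by = 15)
  member <- ts + 35 >= 1000 & ts + 35 < 1100
  expect_equal(ts[member], c(975, 990, 1005, 1020, 1035, 1050))
  buf2 <- data.frame(j = seq_along(ts), t = ts)
  sel2 <- select_lines(buf2, 1000, 1100, delta = 35)
  expect_equal(sel2$set$t, ts[member])
  # stale lines are dropped, unselected future lines are retained
  expect_equal(sel2$buffer$t, 1065)
})

test_that("every buffered line is assigned to exactly one interval over a run", {
  res <- fx_translation_result()
  expect_false(any(duplicated(res$line_log$j)))
  scan <- fx_translation_scan()
  # all lines between the first and last accepted frame were stitched
  ok_t <- res$frame_log$t[res$frame_log$verdict == "ok" |
                            res$frame_log$stage == "bootstrap"]
  tc <- scan$lines$t + 35
  expected <- which(tc >= min(ok_t) & tc < max(ok_t))
  expect_setequal(res$line_log$j, expected)
})

test_that("false-color mapping is exact for gray mode and monotone", {
  z <- matrix(0, 540, 100)
  expect_true(all(false_color(z, "gray") == 0))
  cst <- matrix(0.42, 540, 100)
  expect_equal(false_color(cst, "gray")[, 1], rep(0.42, 540))
  rng <- fx_rng(3L)
  a <- matrix(rng$runif(540 * 100), 540, 100)
  fc <- false_color(a, "gray")
  ord <- order(rowMeans(a))
  expect_true(all(diff(fc[ord, 1]) >= 0))
  expect_error(false_color(a, "plasma"), "unknown false-color mode")
  # band_rgb picks the configured wavelengths
  fb <- false_color(a, "band_rgb", bands = c(620, 550, 500))
  expect_equal(fb[, 3], hsistitch:::clamp(a[, 1], 0, 1))  # 500 nm = band 1
})

test_that("homography interpolation hits the left endpoint and stays convex", {
  Hp <- hg_translation(3, 1)
  out <- interpolate_homographies(Hp, hg_translation(9, 7), 3L)
  expect_identical(out[[1L]], hg_normalize(Hp))  # k = 0: exactly H_prev
  same <- interpolate_homographies(Hp, Hp, 5L)
  for (h in same) expect_equal(h, hg_normalize(Hp))
  # element-wise average of normalized matrices: I and T(4,0), n=2, k=1
  mid <- interpolate_homographies(hg_identity(), hg_translation(4, 0), 2L)
  expect_equal(mid[[2L]], hg_translation(2, 0))
  expect_error(interpolate_homographies(Hp, Hp, 0L), "at least 1")
})

test_that("conjugation equals sequential coordinate conversion (point oracle)", {
  expect_equal(adjust_for_line(hg_translation(5, 6), hg_identity(),
                               hg_identity()), hg_translation(5, 6))
  rng <- fx_rng(17L)
  for (case in 1:100) {
    H <- fx_random_H(rng)
    H_sens <- fx_random_H(rng, scale = 0.3)
    H_pos <- hg_translation(rng$runif(1, 0, 500), rng$runif(1, -5, 5))
    Hp <- adjust_for_line(H, H_sens, H_pos)
    expect_lt(max(abs(adjust_for_line(hg_identity(), H_sens, H_pos) -
                        diag(3))), 1e-9)
    pts <- cbind(rng$runif(5, 0, 1), rng$runif(5, 0, 540))
    seq_path <- hg_apply(solve(H_pos),
                         hg_apply(solve(H_sens),
                                  hg_apply(H,
                                           hg_apply(H_sens,
                                                    hg_apply(H_pos, pts)))))
    expect_lt(max(abs(hg_apply(Hp, pts) - seq_path)), 1e-9)
  }
})

test_that("adaptive width divides the corner translation and caps at 8", {
  h <- 540L
  expect_equal(adaptive_width(hg_translation(21, 0), h, 7L), 3L)
  expect_equal(adaptive_width(hg_translation(15, 0), h, 7L), 3L)  # ceiling
  expect_equal(adaptive_width(hg_translation(100, 0), h, 7L), 8L) # cap
  expect_equal(adaptive_width(hg_translation(0, 50), h, 7L), 1L)  # >= 1
  expect_equal(adaptive_width(hg_translation(100, 0), h, 7L,
                              adaptive = FALSE, fixed_width = 3L), 3L)
})

test_that("offset updates pad the canvas only leftwards/upwards as needed", {
  st <- panorama_state()
  st <- update_offset(st, list(xmin = 0, xmax = 9, ymin = 0, ymax = 9))$state
  st$canvas[, , ] <- 0.5
  st$mask[, ] <- TRUE
  d0 <- dim(st$mask)

  up <- update_offset(st, list(xmin = -5, xmax = 9, ymin = 3, ymax = 9))
  expect_equal(up$H_T, hg_translation(5, 0))
  expect_equal(dim(up$state$mask), d0 + c(0L, 5L))
  expect_equal(up$state$H_offset, hg_translation(5, 0))
  expect_false(any(up$state$mask[, 1:5]))  # new padding is empty

  noop <- update_offset(up$state, list(xmin = 2, xmax = 8, ymin = 2,
                                       ymax = 8))
  expect_identical(noop$state$canvas, up$state$canvas)
  expect_equal(noop$H_T, hg_identity())

  both <- update_offset(panorama_state(),
                        list(xmin = -5, xmax = 1, ymin = -7, ymax = 1))
  expect_equal(both$H_T, hg_translation(5, 7))
})

test_that("compositing is newest-wins and disjoint lines add occupancy", {
  gray <- function(v) cbind(rep(v, 540), rep(v, 540), rep(v, 540))
  one <- warp_and_composite(list(gray(0.8)), list(hg_identity()), 1L, 1,
                            panorama_state())
  two <- warp_and_composite(list(gray(0.8), gray(0.8)),
                            list(hg_identity(), hg_identity()),
                            c(1L, 1L), c(1, 1), panorama_state())
  expect_identical(one$canvas, two$canvas)
  expect_identical(one$mask, two$mask)

  # newer line overwrites the older at the same place
  newer <- warp_and_composite(list(gray(0.2), gray(0.9)),
                              list(hg_identity(), hg_identity()),
                              c(1L, 1L), c(1, 1), panorama_state())
  expect_equal(unique(newer$canvas[newer$mask]), 0.9)

  disj <- warp_and_composite(list(gray(0.3), gray(0.6)),
                             list(hg_identity(), hg_translation(10, 0)),
                             c(1L, 1L), c(1, 1), panorama_state())
  expect_equal(sum(disj$mask), 2L * sum(one$mask))
})

test_that("widening extends in the motion direction, keeping the source column fixed", {
  gray <- cbind(rep(0.5, 540), rep(0.5, 540), rep(0.5, 540))
  fwd <- warp_and_composite(list(gray), list(hg_translation(20, 0)), 4L, 1,
                            panorama_state())
  occ_cols <- which(colSums(fwd$mask) > 0) - 1L
  expect_equal(range(occ_cols), c(20L, 23L))  # [x0, x0 + w)
  bwd <- warp_and_composite(list(gray), list(hg_translation(20, 0)), 4L, -1,
                            panorama_state())
  occ_cols_b <- which(colSums(bwd$mask) > 0) - 1L
  expect_equal(range(occ_cols_b), c(17L, 20L))  # trailing duplication
})

test_that("the forget-function crops bit-exactly and preserves global placement", {
  rng <- fx_rng(23L)
  st <- panorama_state()
  st <- update_offset(st, list(xmin = 0, xmax = 399, ymin = 0,
                               ymax = 99))$state
  st$canvas[] <- rng$runif(length(st$canvas))
  st$mask[] <- TRUE
  win <- list(xmin = 200, xmax = 280, ymin = 10, ymax = 90)
  cropped <- crop_forget(st, win, margin = 100)
  # content beyond window + margin goes on both sides: keep [100, 380]
  expect_equal(ncol(cropped$mask), 281L)
  expect_equal(cropped$H_offset, hg_translation(-100, 0) %*% st$H_offset)
  # retained pixels bit-identical
  expect_identical(cropped$canvas, st$canvas[, 101:381, , drop = FALSE])

  inside <- crop_forget(st, list(xmin = 0, xmax = 399, ymin = 0, ymax = 99),
                        margin = 100)
  expect_identical(inside, st)
})

test_that("cropping then stitching equals never cropping near the window", {
  gray <- function(v) cbind(rep(v, 540), rep(v, 540), rep(v, 540))
  mk <- function(do_crop) {
    st <- panorama_state()
    st <- warp_and_composite(list(gray(0.4)), list(hg_translation(300, 0)),
                             3L, 1, st)
    st <- warp_and_composite(list(gray(0.7)), list(hg_translation(600, 0)),
                             3L, 1, st)
    if (do_crop) {
      st <- crop_forget(st, list(xmin = 560, xmax = 700, ymin = 0,
                                 ymax = 539), margin = 100)
    }
    st <- warp_and_composite(list(gray(0.9)), list(hg_translation(630, 0)),
                             3L, 1, st)
    st
  }
  a <- mk(TRUE)
  b <- mk(FALSE)
  # compare on the window region in global coordinates
  for (gx in 600:630) {
    pa <- hg_apply(a$H_offset, c(gx, 200))
    pb <- hg_apply(b$H_offset, c(gx, 200))
    expect_equal(a$canvas[pa[2] + 1, pa[1] + 1, ],
                 b$canvas[pb[2] + 1, pb[1] + 1, ])
    expect_equal(a$mask[pa[2] + 1, pa[1] + 1],
                 b$mask[pb[2] + 1, pb[1] + 1])
  }
})

test_that("a line warped absurdly far away is skipped with a warning", {
  gray <- cbind(rep(0.5, 540), rep(0.5, 540), rep(0.5, 540))
  expect_warning(
    st <- warp_and_composite(list(gray), list(hg_translation(5e5, 0)), 1L,
                             1, panorama_state()),
    "sanity")
  expect_null(st$canvas)
})
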