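# Shared fixtures, built once per test run and cached. All simulated scans
# use zero or low noise on a textured scene so registration accuracy is
# limited by the pipeline, not by the imagery.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, build) {
  got <- get0(key, .fx)
  if (is.null(got)) {
    got <- build()
    assign(key, got, .fx)
  }
  got
}

fx_scene <- function(kind = "texture", seed = 0L) {
  fx_cached(paste0("scene_", kind, "_", seed), function() {
    generate_scene(seed, kind, 1600L, 900L)
  })
}

# 20-frame, 2 px/frame zero-noise translation scan + ingest + stitch result
fx_translation_scan <- function() {
  fx_cached("scan_trans", function() {
    traj <- make_trajectory("translation", 20L, speed = 2,
                            start_x = 520, start_y = 460)
    simulate_scan(fx_scene(), traj, seed = 1L)
  })
}

fx_translation_streams <- function() {
  fx_cached("streams_trans", function() ingest(fx_translation_scan()))
}

fx_translation_result <- function() {
  fx_cached("result_trans", function() {
    stitch_scan(fx_translation_streams(), stitch_config(seed = 11L))
  })
}

# one preprocessed frame (plenty of texture) for detector tests
fx_frame <- function() fx_translation_streams()$frames[[1L]]

# random normalized homography near identity (well-conditioned)
fx_random_H <- function(rng, scale = 1) {
  H <- diag(3) + matrix(c(rng$runif(6L, -0.05, 0.05) * scale,
                          rng$runif(2L, -1e-4, 1e-4) * scale, 0),
                        3L, 3L, byrow = TRUE)
  H[1L, 3L] <- rng$runif(1L, -20, 20) * scale
  H[2L, 3L] <- rng$runif(1L, -20, 20) * scale
  H / H[3L, 3L]
}

# deterministic uniform/normal streams for tests (keeps the global RNG
# state of the test runner untouched)
fx_rng <- function(seed) hsistitch:::local_rng(seed)

# build a trajectory object from explicit pose columns
fx_custom_trajectory <- function(tx, ty, rot = 0, scale = 1) {
  n <- length(tx)
  structure(
    list(poses = data.frame(frame = seq_len(n) - 1L, tx = tx,
                            ty = rep_len(ty, n), rot_deg = rep_len(rot, n),
                            scale = rep_len(scale, n), px = 0, py = 0),
         kind = "custom", speed = NA_real_),
    class = "hsistitch_trajectory")
}
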