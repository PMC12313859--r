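# hsistitch

Freehand line-scan hyperspectral panorama stitching.

## What problem this solves

Push-broom hyperspectral laparoscopes record a high-resolution RGB video
of the field of view alongside a one-pixel-wide vertical line of spectral
data (1×540 px, 100 bands, 500–1000 nm) whose slit sits at the center
column of the color image. Capturing a full hyperspectral image normally
means sweeping the slit with an internal motor for several seconds while
the camera and the scene hold perfectly still — which operating rooms do
not offer. The alternative implemented here: the operator sweeps the
*camera* freehand, the pipeline estimates the camera motion from the RGB
stream, transfers it to the temporally corresponding spectral lines, and
composites the lines into an incrementally growing false-color panorama
overlaid on the live video.

`hsistitch` is a full re-implementation of that pipeline for R, aimed at
researchers in biomedical image analysis who want to study, evaluate, or
extend the method without the camera hardware: it ships a synthetic
dual-sensor scanner that emulates both streams from rendered planar
scenes under known camera trajectories, with exact per-timestamp
ground-truth homographies for automatic accuracy evaluation.

## The method in brief

The scene is modelled as a plane, so views are related by 3×3
homographies. Per incoming RGB frame `I_i`:

1. **Preprocess** — undistort via a precomputed calibration map, CLAHE
   (clip limit 2.0, 8×8 tiles), timestamp.
2. **Local picking** — up to 1000 salient keypoints with 256-bit binary
   descriptors; brute-force Hamming matching to the previous frame with
   Lowe's ratio 0.8; RANSAC homography `H_(i,i-1)` (confidence 0.995,
   threshold 8 px); plausibility gate (≥40 inliers, motion neither
   negligible nor excessive, no abnormal distortion). Twenty consecutive
   invalid frames reset the panorama.
3. **Global registration** — match against a bounded database of panorama
   keypoints (caps 500 ranked matches / 50 additions / 200 updates / age
   limit 80) and estimate the frame-to-panorama homography `H_(i,P)`.
4. **Line stitching** — select the spectral lines with
   `t_(i-1) ≤ t̃_j + δ < t_i` (δ ≈ 35 ms), interpolate homographies
   across the interval, conjugate into slit coordinates with the
   calibration homographies `H_sens`, `H_pos`, widen each line adaptively
   (`w̃ = ⌈T/n⌉`, capped at 8 px), and composite newest-wins onto the
   canvas, with an offset homography keeping coordinates non-negative and
   a forget-function cropping 100 px beyond the display window.
5. **Visualization** — warp the panorama into the current view with the
   inverse of the latest final homography and alpha-blend it onto the
   frame.

Accuracy is quantified as the Euclidean distance between landmark pairs
on the RGB view and the panorama (median, IQR), converted to millimetres
by cross-multiplication — at a 50 mm working distance, 960 px span 85 mm.

## Worked example

```r
library(hsistitch)

scene <- generate_scene(seed = 0, kind = "texture")
traj  <- make_trajectory("freehand", n_frames = 30, speed = 2, seed = 0)
scan  <- simulate_scan(scene, traj, noise_sd = 0.005, seed = 0)
scan
#> <hsistitch_scan> 30 frames @ 10 fps, 210 lines @ 70 fps, delta=35 ms

res <- stitch_scan(ingest(scan), stitch_config(seed = 0))
res
#> <hsistitch_result> 30 frames (30 ok), 203 lines stitched, 0 resets

report <- auto_ground_truth_error(res, scan$gt, n_landmarks = 100, seed = 1,
                                  image_width_px = 960, section_width_mm = 85)
report
#> <error report> n=100 median=0.02 px (IQR 0.01-0.03), max=0.06 px
#>   at 0.0885 mm/px: median=0.002 mm, 95th pct=0.004 mm
```

The scan simulates three seconds of freehand sweeping (30 RGB frames, 210
spectral lines, the line stream delayed by 35 ms as in the real sensor
pair). All 30 frames pass the plausibility gates and 203 lines are
composited (the handful emitted before the first frame's interval cannot
be assigned). The report compares, for 100 random landmarks, where the
pipeline placed each scene point on the panorama against where the
simulator's ground truth says it belongs: here the median registration
error is 0.02 px (≈0.002 mm at the reference working distance) — the
synthetic scene satisfies the method's planarity assumption exactly, so
errors are far below what physical recordings show.

The panorama itself is `res$panorama$canvas` (a false-color RGB array
with occupancy mask `res$panorama$mask`), and
`render_overlay(frame, res$panorama, calibration = scan$calibration)`
produces the blended augmented view. A thin command-line front end with
`simulate` / `stitch` / `render` / `evaluate` subcommands is installed at
`inst/cli/hsistitch.R`.

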