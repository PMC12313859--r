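---
title: "Freehand line-scan hyperspectral stitching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Freehand line-scan hyperspectral stitching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Laparoscopic hyperspectral cameras of the push-broom type record two
asynchronous streams: a color video of the field of view (here 960×540 px
at a nominal 10 fps) and a one-pixel-wide vertical line of hyperspectral
data (1×540 px, 100 bands spanning 500–1000 nm at 5 nm spacing, nominal
70 fps) acquired by a line spectrograph whose entrance slit sits at the
center column of the color view. A full hyperspectral capture normally
requires a motor to sweep the slit across the scene over several seconds,
during which nothing may move — a serious constraint intraoperatively.

`hsistitch` implements the alternative: the operator sweeps the
*laparoscope* freehand. Camera motion is estimated from the RGB video,
transferred to the temporally corresponding spectral lines, and the lines
are composited into an incrementally growing, globally registered
false-color panorama that is blended back onto the live color view. The
package also contains a synthetic dual-sensor scanner, so that every stage
can be tested against exact ground-truth motion without any hardware.

## Registration model

All geometry is projective: the scene is modelled as a plane, so any two
views are related by a 3×3 homography acting on homogeneous pixel
coordinates, with the origin at the image's upper-left corner. Between
consecutive frames the pipeline estimates the *local* homography
$H_{(i,i-1)} : I_i \mapsto I_{i-1}$ from matched keypoints; against the
accumulated panorama it estimates the *global* homography
$H_{(i,P)} : I_i \mapsto P$. Local registration exists for quality control
— inlier screening, motion detection, and plausibility gating — while the
global registration, anchored in a bounded database of panorama keypoints,
is what limits drift. The global coordinate system is fixed by the first
frame of a stitching sequence and never changes; only the canvas offset
(a pure translation $H^T$) moves as the panorama grows to the left or top.

Keypoints are salient corners with 256-bit binary descriptors: the package
uses a Harris response with subpixel refinement plus a BRIEF-style
comparison pattern, matched brute-force under the Hamming norm with Lowe's
ratio test (0.8, strict inequality) and one-to-one duplicate resolution.
Homographies are estimated by 4-point DLT RANSAC at confidence 0.995 with
an 8.0 px reprojection threshold, refit on the consensus set by
least-squares DLT with Hartley normalization.

### Plausibility gating

An estimated homography passes through four checks, in order:

1. **no motion** — maximum warped-corner displacement below 2 px. The frame
   is skipped without penalty: re-registering an almost static view wastes
   computation and inflates the keypoint database. The next frame is
   compared against the last *processed* frame, so slow scans advance in
   multi-frame steps and no data is lost (the line intervals span skipped
   frames).
2. **low inliers** — fewer than 40 RANSAC inliers.
3. **distorted** — the warped corner quadrilateral is non-convex, flips
   orientation, or changes area beyond a factor in [0.5, 2.0]. This check
   deliberately precedes the displacement check: a mirror or area blow-up
   also displaces corners, but "distorted" is the more specific diagnosis.
4. **excessive motion** — corner displacement beyond 25% of the frame
   width.

Twenty *consecutive* failing frames (no-motion skips do not count) reset
the panorama and start a new sequence. The thresholds in 1, 3 and 4 are
package defaults exposed through `stitch_config()`; the named checks are
part of the method, their numeric values are empirical.

At the global stage the same gate is applied to the *incremental*
transform $H_{(i-1,P)}^{-1} H_{(i,P)}$ rather than to $H_{(i,P)}$ itself:
the global homography legitimately accumulates the entire scan's motion,
so gating it directly would always trip the excessive-motion bound. The
minimum-motion check is disabled there because motion has already been
assessed frame-to-frame.

### Keypoint database maintenance

After each processed frame, each current keypoint falls into one of three
outcomes: **no match** → it is new, and the 50 strongest unmatched
keypoints are added with coordinates warped into the global system by
$H_{(i,P)}$; **inlier match** → the entry is refreshed (the 200
lowest-Hamming-distance inliers get the warped current coordinates and the
current descriptor; every inlier's age is zeroed); **outlier match**, or
any match involved in an implausible homography → the entry is deleted as
an uncertainty factor. All other entries age by one frame and entries
unmatched for more than 80 processed frames are evicted. Only the 500
best-ranked matches feed the global estimation. These four caps
(500/50/200/80) bound database size and matching cost, producing the
plateau that keeps the pipeline real-time-capable.

Two points were genuinely open and decided here: the first frame of a
sequence seeds the database with *all* its extracted keypoints (the 50-cap
regulates growth during maintenance, not the bootstrap — a 50-point seed
would starve the second frame's registration), and refreshed coordinates
come from warping the current detection rather than averaging with the
stored position (the newer observation is treated as the more reliable
one).

## From frame homographies to line placements

Lines are buffered and assigned to inter-frame intervals by the
delay-corrected, half-open membership rule
$\tilde{\mathcal{L}}_i = \{\tilde I_j \mid t_{i-1} \le \tilde t_j + \delta < t_i\}$,
with $\delta$ = 35 ms by default; at nominal rates about seven lines fall
in each interval. Each line's homography is the element-wise convex
combination
$H_{(k,P)} = (1 - k/n) H_{(i-1,P)} + (k/n) H_{(i,P)}$, $k = 0 \dots n-1$,
of the interval's two global homographies, both normalized to bottom-right
element 1 and renormalized afterwards. Note the divisor: the current
frame's homography is approached but never attained within an interval —
this is reproduced as specified, and at nominal rates (7 lines per 100 ms)
the mismatch against true time interpolation is below a seventh of the
per-frame motion. $H_{(i-1,P)}$ is the identity at sequence start.

Frame homographies act on RGB coordinates; lines live in the slit's
coordinate system, displaced to the frame center by $H_{pos}$ and tilted
into the spectrograph's image plane by $H_{sens}$. Both are calibration
inputs, never estimated here. The conjugation
$H'_{(k,P)} = H_{pos}^{-1} H_{sens}^{-1} H_{(k,P)} H_{sens} H_{pos}$
carries a line-local coordinate into the RGB frame, applies the mapping,
and carries it back. The final per-line warp adds the canvas offset:
$H^{final}_k = H^T_j H'_{(k,P)}$. A property test verifies on 1000 random
calibrations that the composed matrix and the sequential five-step point
mapping agree to below $10^{-9}$.

### Adaptive line width

A one-pixel line at 70 fps covers the canvas only at very slow sweeps. The
incremental line-plane transform
$H'_{(i,i-1)} = H'^{-1}_{(i-1,P)} H'_{(i,P)}$ is applied to the four
corners of a 1×540 line ((0,0), (1,0), (0,540), (1,540)); the largest
absolute horizontal corner translation $T_i$, divided by the interval's
line count and rounded up, $\tilde w_i = \lceil T_i / n \rceil$, gives the
duplication width, capped at 8 px and floored at 1. The duplicated columns
extend in the direction of motion (sign of the mean horizontal corner
translation), so the physical column keeps its true position — the spec of
the duplication leaves the anchor open, and anchoring at the source column
keeps the placement error one-sided and below $\tilde w$. With the
adaptive feature disabled a fixed width (3 px, the setting used for
annotation-based evaluation of the physical system) is used instead.

### Compositing, offset, and the forget-function

Widened lines are warped by inverse mapping with nearest-neighbour
sampling — this preserves both the piece-wise-constant model of duplicated
columns and the *newest-wins* overwrite semantics (overlapping content is
replaced by the newer line, keeping the panorama up to date). When a
line's warped extent reaches negative coordinates, the canvas is padded on
the left/top and $H^T$ accumulates the corresponding translation; growth
to the right/bottom needs no offset. After each frame, canvas regions more
than 100 px beyond the current display window are cropped (the
"forget-function"), with $H^T$ adjusted so retained content keeps its
global placement bit-exactly. A line whose transform lands beyond ten
display diagonals is skipped with a warning rather than exploding the
canvas.

False-color preparation is pluggable: `"gray"` maps each pixel to its
band-mean reflectance (the exact inverse of the synthetic scanner's
spectral model, enabling pixel-level comparisons), `"band_rgb"` maps three
chosen wavelengths to R, G, B. The overlay renderer warps the panorama by
the inverse of the most recent final homography into the current view and
applies a linear blend (`alpha` = 0.5 by default; the blend weight is a
display preference, not part of the method) on occupied pixels only.

## The synthetic scanner

`generate_scene()` renders planar, achromatic targets: `"usaf"`
(high-contrast axis-aligned bar triplets at four scales on a lightly
textured background, the desk-scale analogue of a resolution chart) and
`"texture"` (a smooth multi-scale random field emulating a printed
surgical still). The texture field is deliberately band-limited with its
finest structure at ~4 px: a printed target imaged through real optics
carries no per-pixel white noise, and a band-limited albedo is what makes
sub-pixel raster comparisons between panorama and scene meaningful — with
a mean albedo gradient of ~0.02 per px and sub-pixel placement offsets the
expected panorama-vs-scene discrepancy stays below 2 intensity levels
(8-bit), which is exactly what the end-to-end test checks.

`simulate_scan()` moves a virtual 960×540 camera along a trajectory (one
pose per frame; translation / rotation / scale / perspective families or a
`freehand` combination with smooth pseudo-random phases), rendering frames
as bilinear crops of the scene and lines as the scene column under the
slit at the line's timestamp, with poses linearly interpolated between
frame times — mirroring the interpolation assumption the stitching stage
itself makes, so tests measure the pipeline's interpolation error rather
than a simulation artifact. Each albedo value $a$ becomes the 100-band
spectrum $a \cdot s(\lambda)$ with $s$ a fixed smooth unit-mean profile.
Timestamps are integer milliseconds; emitted line timestamps are shifted
by $-\delta$ so the pipeline's $+\delta$ correction re-synchronizes them.
Barrel distortion and vignetting are available through the calibration
bundle but off by default: accuracy tests need a clean geometric oracle,
robustness tests can switch them on. What the simulator does *not* model:
3-D structure and parallax (the method itself assumes planarity),
photorealistic tissue, illumination flicker, or timestamp jitter beyond
millisecond quantization — so passing tests demonstrate correctness of
the geometry pipeline under its own assumptions, not robustness to
violations of them.

## Evaluation

`registration_error()` summarizes landmark-pair Euclidean distances by
median and IQR (quartiles by linear interpolation between order
statistics, R's default type 7 — the convention was unspecified and is
declared here); `px_to_mm()` converts via cross-multiplication, e.g. at a
50 mm working distance a 960 px frame spans 85 mm, so 2.2 px ≈ 0.2 mm.
`auto_ground_truth_error()` replaces manual annotation on simulated scans:
scene points within the scanned strip are mapped once through the
ground-truth chain and once through the homographies the pipeline actually
used, both into the line-plane global system (the canvas offset is common
to both and cancels), and the displacement is the registration error.
`speed_sweep()` repeats simulate–stitch–evaluate across scanning speeds
and fits the linear speed–error relation, marking speeds where
registration breaks down as failed.

## Problem sizes and reproducibility

The test suite and the acceptance script run desk-scale stand-ins chosen
to exercise every stage at realistic rates: a 105-frame (~735-line)
constant-velocity translation scan at 1 px per frame interval for the
median-error protocol, ten 40-frame freehand scans at 1–3 px per frame
interval (seeds 0–9, noise s.d. 0.005) for the 95th-percentile protocol,
and 12–26-frame scans for unit-level properties. All randomness — scene
synthesis, trajectory phases, sensor noise, RANSAC, landmark sampling —
flows from explicit integer seeds through a private RNG that never touches
the session's random state, so every number in the test suite is exactly
reproducible.

## Known limitations

The planarity assumption is inherited from the method: scenes with depth
variation would violate the single-homography model. The binary
descriptors here are unoriented; per-frame rotations are small in the
simulated trajectories and the database's descriptor refresh keeps global
matching viable under slowly accumulating rotation, but rotation-heavy
scans beyond the tested ±5° range would degrade matching faster than an
oriented descriptor would. Element-wise homography interpolation is exact
for translations and a first-order approximation for rotational /
projective motion between frames. Seam intensity artifacts from vignetting
are reproduced, not corrected (newest-wins replacement, no blending across
overlaps, matching the method's behaviour).
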