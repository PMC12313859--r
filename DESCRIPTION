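Package: hsistitch
Title: Freehand Line-Scan Hyperspectral Panorama Stitching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Real-time style stitching of one-pixel-wide hyperspectral
    line-scan data into an incrementally growing, globally registered
    false-color panorama, driven by camera motion estimated from a
    temporally coupled RGB video stream. Includes frame preprocessing
    (undistortion, CLAHE), keypoint-based frame-to-frame and
    frame-to-panorama homography registration with a bounded panorama
    keypoint database, temporal line selection and homography
    interpolation, adaptive line widening, newest-wins compositing with
    offset and forget handling, overlay rendering, registration-error
    evaluation, and a synthetic dual-sensor scanner that emulates both
    streams from rendered planar scenes with per-timestamp ground-truth
    homographies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    methods,
    Matrix,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
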