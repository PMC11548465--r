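Package: fruitrack
Title: Tracking-by-Detection Fruit Counting in Orchard Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts fruit in orchard videos by tracking-by-detection. Implements
    the MR-SORT (Multiple Rematching SORT) multi-object tracker: constant-velocity
    Kalman prediction with sparse-keypoint camera-motion compensation, two-stage
    confidence-split data association on intersection-over-union via a Hungarian
    assignment solver, and appearance-based rematching of leftover detections
    using VLAD (Vector of Locally Aggregated Descriptors) signatures guarded by a
    relative-displacement validation mechanism. Also provides forward-only
    reference implementations of attention-modulated dynamic convolution, a
    global channel/spatial attention gate, soft pooling and a soft spatial
    pyramid pooling layer; MOTChallenge-style file input/output and annotation
    geometry conversions; CLEAR-MOT tracking metrics (MOTA, ID switches),
    detection metrics (precision, recall, average precision) and per-video
    relative counting error; and a seeded synthetic orchard simulator producing
    frames, ground truth and corrupted detections for end-to-end evaluation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
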