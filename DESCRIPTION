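Package: cehd
Title: Corn Ear Height Detection from RGB-D Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-detection stack for measuring corn ear heights from an
    RGB-D camera mounted on a moving field platform. Refines detector box
    scores from regression-distribution statistics with an occlusion-aware
    gate, removes detections from non-target planting rows by depth, tracks
    ears across frames with a DeepSORT-style association loop driven by an
    independent-dimension adaptive Kalman filter, and estimates each ear's
    height above ground from the median of the back-projected in-box depth
    point cloud. Ships a seeded synthetic field-scene simulator with full
    ground truth, CLEAR-MOT and height-accuracy evaluation metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
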