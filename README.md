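# cehd — corn ear height detection from RGB-D detection streams

`cehd` is the post-detection stack of a corn ear height measurement
system for row-following harvest platforms. Given per-frame detector
output (boxes + confidences, optionally appearance embeddings and
box-regression distributions), aligned depth maps, and the camera's
mount geometry (height 1.8 m, pitch 45° by default), it produces stable
per-ear tracks and each ear's height above ground.

The pipeline:

1. **Score refinement** — per-side box-regression distributions are
   softmaxed, summarized by top-k statistics, scored by a small MLP into
   a quality score `Q`, and fused with the classification score `S`
   through an occlusion factor `O = σ(S)`: additively `S' = S + Q·O` or
   multiplicatively `S' = S·σ(Q)·O`, with an output gate at `S' ≥ 0.75`.
2. **Row filtering** — detections in the next planting row (0.6 m
   spacing) are removed by a 0.5 m range threshold on the box's median
   depth, compared in the horizontal ground plane so the cut is
   independent of ear height.
3. **Tracking** — a DeepSORT-style cascade (appearance cosine matching
   under Mahalanobis gating, Hungarian assignment, IoU fallback) driven
   by a constant-velocity Kalman filter whose observation noise adapts
   per dimension to detection confidence `c`:
   `σ_x = max(1−c, ε)·w·h`, `σ_y = max(1−0.8c, ε)·w·h`,
   `σ_a = max(1−0.5c, ε)·0.1`, `σ_h = max(1−c, ε)·w·h` (ε = 0.01,
   w = 0.05), plus exponential smoothing of the reported center
   (`s_t = α·s_{t−1} + (1−α)·x'_t`, α = 0.7, velocity-compensated for
   the moving platform).
4. **Height solving** — depth pixels inside each tracked box are
   back-projected to a point cloud, depth outliers removed by a
   median ± 3·MAD rule, each point converted to height above ground via
   `H = mount − (y_c·cosα + z_c·sinα)`, and the per-box median reported,
   with a running median per track.

A seeded simulator (`generate_scene()`, `simulate_scene()`) generates
the full data regime — depth frames, ground-truth identities and
heights, confidence-dependent detection noise, occlusion episodes,
clustered embeddings — so everything is testable without field data.
Evaluation utilities implement detection precision/recall at IoU 0.5,
height MAE and Pearson r, center-RMSE curves, and CLEAR-MOT / identity
metrics (MOTA, IDF1, ID switches).

## Worked example

Simulate a two-row scene, run the pipeline, and evaluate:

```r
library(cehd)

scene <- tempfile("scene"); out <- tempfile("out")
cfg <- scene_config(n_ears_target_row = 4, n_ears_far_row = 2,
                    frames = 30, seed = 77)
simulate_scene(cfg, scene)

run_pipeline(det_path   = file.path(scene, "det.txt"),
             depth_dir  = scene,
             camera_path = file.path(scene, "camera.yaml"),
             out_dir = out, seed = 77)

tracks <- read_tracks(file.path(out, "tracks.csv"))
gt <- read.csv(file.path(scene, "gt.csv")); gt$frame <- gt$frame - 1
m <- mot_metrics(tracks, gt[gt$row == "target", ])
unlist(m[c("mota", "idf1", "id_switches")])
#>        mota        idf1 id_switches
#>           1           1           0

summary <- read.csv(file.path(out, "height_summary.csv"))
head(summary, 3)
#>   track_id height_median_m height_mad_m n_frames
#> 1        1        1.397397     0.001572       30
#> 2        2        1.393348     0.001425       20
#> 3        3        1.199623     0.001234       10
```

The tracker keeps every target-row ear on a single identity (MOTA and
IDF1 of 1, no switches — the far-row ears were removed by the depth
filter), and `height_summary.csv` reports each track's median height
above ground in meters with its MAD spread: track 1's ear is measured
at 1.397 m with about 1.6 mm of frame-to-frame scatter, against a true
height of 1.396 m in the scene's `gt_heights.csv`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cehd.R simulate --out scene --seed 7
Rscript inst/cli/cehd.R track --det scene/det.txt --depth-dir scene \
        --camera scene/camera.yaml --out run
Rscript inst/cli/cehd.R evaluate --gt scene/gt.csv --tracks run/tracks.csv
Rscript inst/cli/cehd.R benchmark-occlusion --seeds 50
```

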