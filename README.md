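# nematrack

Posture tracking of crawling *C. elegans* and the statistics of tracker
comparison, as a self-contained, fully testable R package.

## The problem

High-throughput behavioural screens film dozens of worms per well and reduce
each animal, frame by frame, to a **skeleton** (an ordered head-to-tail
midline of N points). Classical contour-based trackers fail exactly where the
biology gets interesting: coiled (self-intersecting) postures, worm-worm
overlaps, and low-contrast thick bacterial lawns. Modern grid-cell
("YOLO-style") detectors predict skeletons directly from raw pixels and keep
identities through collisions — but their pipelines involve many interacting
parts (background model, shape space, grid decoding, temporal interpolation,
linking, metrics), each easy to get subtly wrong.

`nematrack` implements that whole pipeline at desk scale, with a synthetic
crawling-worm video generator supplying exact ground truth, so every stage is
verifiable against an oracle:

- **`simulate_recording()` / `sample_clip()` / `synthesize_overlaps()`** —
  serpenoid worms (undulation $\kappa(s,t)=a\sin(2\pi s/\lambda-\varphi t)$,
  constant arclength, optional dwelling and coiling) on static non-uniform
  backgrounds with egg-like distractors; 11-frame training clips strided over
  2/4/8 s windows with the 3 central frames annotated; overlap scenes built
  by pairing single-worm clips and stacking them darkest-pixel-wise
  (a 50,000-clip pool yields 25,000 stacked clips).
- **`estimate_background()` / `subtract_background()`** — rank-1 SVD of
  1:400 temporally subsampled frames; the top singular mode is the static
  background.
- **`fit_shape_space()` / `encode_skeleton()` / `decode_skeleton()`** — the
  eigenworm PCA basis (D = 72 full scale) over equal-arclength, head-tail
  oriented skeletons, encoded relative to the predicting grid cell's centre.
- **`assign_targets()` / `decode_grid()` / `deduplicate()`** — the grid
  contract: 16 px cells (32 × 32 for a 512 × 512 input padded to a multiple
  of 16), K = 8 slots per cell, 48 px assignment cutoff, confidence
  threshold 0.5, greedy non-maximum suppression.
- **`mini_train()` / `predict_clip()`** — a deliberately small seeded
  reference network (one strided patch-linear layer + heads) that exercises
  the training/decoding contract on 64 × 64 clips in minutes on a CPU.
- **`downsample_frames()` / `interpolate_spline()`** — 1:3 temporal thinning
  and cubic smoothing-spline interpolation in (x, y, t) with one shared
  GCV-chosen smoothing parameter.
- **`link_detections()` / `nearest_neighbour_link()`** — optimal (Hungarian)
  frame-to-frame assignment on spatial + latent cost with gap bridging,
  versus the greedy centroid baseline used for the ablation.
- **`skeleton_rmsd()` / `nearest_segment_distance()` / `classify_failure()` /
  `tracking_fidelity()`** — evaluation: head-tail aligned point-to-point
  RMSD, midline-to-polyline distance, the per-method failure rules, and
  tracking fidelity $1-\sum_t \mathrm{mme}_t / \sum_t g_t$.
- **`basic_features()` / `feature_correlations()` / `feature_f_statistic()` /
  `hedges_d()` / `mean_abs_effect()`** — screen statistics: per-feature
  Pearson r with histogram modal value, one-way F, and Hedge's
  $d = \frac{m_t-m_c}{s_\mathrm{pooled}}\,J$, $J = 1-\frac{3}{4(n_t+n_c)-9}$,
  |d| averaged across doses.

## Worked example

```r
library(nematrack)

# a 2,000-frame recording (400 s at 5 fps) of 3 roaming worms
rec <- simulate_recording(n_worms = 3, duration_s = 400, fps = 5,
                          dim = c(256L, 256L), worm_length = 40,
                          n_points = 25L, worm_width = 3, dwell_prob = 0,
                          speed_range = c(20, 30), seed = 42)
bg <- estimate_background(rec$frames, subsample_step = 20L)
max(abs(bg$image - rec$background))          # vs known true background

# 25 fps scene: shape space, tracking, spline interpolation
rec25 <- simulate_recording(2, 8, fps = 25, dim = c(160L, 160L),
                            worm_length = 40, n_points = 25L,
                            worm_width = 3, seed = 7)
space <- fit_shape_space(unlist(rec25$skeletons, recursive = FALSE), D = 12L)
```

Output actually printed by this session:

```
worm_recording: 2000 frames of 256 x 256 px, 3 worm(s), 5 fps
background_model: 256 x 256 px from 100 frames (step 20)
max background error: 0.0150 (worm contrast 0.30)
shape_space: N = 25 points, D = 12 components
encode/decode residual at D=12: 0.0311 px
track_match_result: 200 frames, sum(mme) = 0, sum(g) = 400, fidelity = 1.0000
spline interpolation RMSE after 1:3 thinning: 0.087 px
Hedge d closed-form example |d|: 0.4041
```

Reading those numbers: the SVD background is within 5% of the worm contrast
at every pixel (the 10% acceptance bound); a 12-component eigenworm basis
reconstructs simulated postures to 0.03 px; Hungarian linking of two
non-colliding worms keeps every identity (fidelity 1.0); thinning a 25 fps
track 1:3 and re-interpolating with smoothing splines costs under 0.1 px;
and the treated = [0, 2] vs control = [1, 3] fixture gives
|d| = 0.7071 × 4/7 ≈ 0.4041.

## Command line

A single entry point covers the pipeline end to end
(`inst/cli/nematrack`, or `nematrack_cli(c(...))` in-process):

```sh
nematrack simulate --n-worms 2 --duration 3 --seed 5 --size 128 \
          --out stack.rds --skeletons-out gt.csv
nematrack subtract-bg --in stack.rds --out resid.rds --step 10
nematrack fit-shapespace --skeletons gt.csv --dim 12 --out space.json
nematrack track --detections gt.csv --out tracks.csv
nematrack evaluate --pred tracks.csv --truth gt.csv --out report.csv
```

Formats are plain text (CSV at full precision, JSON) or RDS; coordinates are
0-based with x = column, y = row, origin top-left.

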