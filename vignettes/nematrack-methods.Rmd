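---
title: "nematrack: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nematrack: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematrack)
```

## What this package is

`nematrack` is a desk-scale, fully testable implementation of a multi-worm
posture-tracking pipeline for crawling *C. elegans* in brightfield video,
together with the statistics used to compare trackers in high-throughput
phenotypic screens. Every stage — synthetic video generation, background
subtraction, the eigenworm shape space, grid-cell detection decoding,
temporal interpolation, trajectory linking, evaluation metrics, and screen
statistics — is exercised end to end on simulated data with known ground
truth, so nothing requires downloads, GPUs, or proprietary formats.

The package deliberately does **not** try to reproduce a production
detector's accuracy on real video. The trainable component here is a tiny
reference network whose job is to exercise the training/decoding *contract*
(target assignment, confidence thresholding, coefficient decoding,
suppression) at a scale a laptop CPU handles in minutes.

## The pipeline and its parameters

### Synthetic worms (module `worm_sim`)

Worms are serpenoid undulators: an inextensible unit-speed curve of fixed
length whose curvature is a travelling wave
$\kappa(s, t) = a \sin(2\pi s/\lambda - \varphi(t))$, laid down behind a head
point that advances along a slowly turning heading. Key defaults, chosen once
to match a 12.4 µm/px, 25 frames/s imaging geometry:

| parameter | default | meaning |
|---|---|---|
| frame size | 512 × 512 px | training-clip geometry |
| worm length | 80 px (~1 mm) | adult at 12.4 µm/px |
| skeleton points N | 49 | the classical midline convention |
| worm width | 4 px | full width, tapering to ~0 at both ends |
| undulation | 0.4–0.6 Hz, λ = 0.9 L | crawling gait |
| speed | 12–18 px/s (~0.15–0.22 mm/s) | on-food crawl |
| contrast | 0.3 | worm darkness below background (0..1 scale) |

Turning uses an Ornstein–Uhlenbeck turn-rate process and rate-limited wall
avoidance, so the body pose is continuous in time — important because the
temporal-spline stage assumes smooth point trajectories. Dwelling (speed 0)
and coiling (curvature amplitude raised until the midline self-intersects)
are optional Markov episodes. Midline arclength is constant *by construction*
(the inextensibility invariant is tested at 1%). Backgrounds are static:
a lawn-edge radial gradient plus dark Gaussian "egg" blobs, both of which the
rank-1 temporal model removes exactly.

What the generator does **not** emulate: photometric noise structure of real
cameras, lawn texture that moves, worm-worm physical interaction during
contact, self-occlusion brightness changes in coils, and mating/aggregation.
A green test here therefore establishes the *logic* of each stage, not
field performance on real plates.

Training clips are 11 frames sampled at uniform stride from 2, 4, or 8 s
windows (stride 5, 10, 20 at 25 fps), annotated only at the three central
frames. Overlap scenes are synthesised by randomly pairing background-
subtracted single-worm clips and combining them pixelwise with the darkest
value — the paperless choice here is the combination rule: a minimum mimics
optical occlusion of dark objects. A pool of 50,000 single-worm clips yields
25,000 stacked two-worm clips, and reshuffling with a new seed re-pairs them.

### Background subtraction (module `background`)

Frames subsampled 1:400 in time form a (pixels × frames) matrix whose highest
energy singular triplet is the background: the unit spatial mode is rescaled
by the singular value times the mean temporal coefficient (the scaling is a
design choice — it puts the estimate in intensity units), and the SVD sign
ambiguity is resolved toward a non-negative spatial mean. Videos shorter than
one step fall back to using every frame. Subtraction is per-video.

A quantitative caveat the tests make explicit: the rank-1 estimate at a pixel
retains roughly `contrast × (fraction of sampled frames in which a worm
covers that pixel)`. Recovery to 10% of worm contrast at *every* pixel
therefore needs sampled frames whose worm configurations decorrelate — long
recordings. The acceptance fixture compresses this into its 2,000-frame
budget by simulating 400 s at 5 frames/s with roaming (non-dwelling) worms
and subsampling 1:20, so ~100 decorrelated frames enter the SVD; with the
default 1:400 step only 5 frames would enter and the bound is provably
unattainable at any implementation. This was decided from that arithmetic,
not tuned on test outcomes.

### Shape space (module `shape_space`)

Skeletons are resampled to N equally spaced points (linear interpolation
along the polyline), head-tail oriented (by reference skeleton when
available, otherwise by the motion heuristic: the end leading the
displacement is the head), flattened to `c(x, y)` vectors, and embedded by
PCA. D = 72 components is the full-scale setting; the desk-scale predictor
uses D = 12, which captures the serpenoid family almost exactly. Grid
encoding subtracts the predicting cell's centre before projection, making
the space translation invariant; note that at truncated D the re-added
offset is reconstructed only up to the out-of-span component of a uniform
translation, which is negligible when translations dominate the training
variance (measured ~4e-5 relative in the test fixtures).

### Grid prediction contract (module `predictor`)

Images pad bottom/right with zeros to a multiple of 16, so pixel coordinates
never shift; a 512 × 512 input yields a 32 × 32 grid of 16 px cells with
K = 8 slots, each carrying a confidence, an L = 8 latent vector, and D
coefficients for each of the 3 annotated frames. Training targets assign a
worm to every cell whose centre is within 48 px of the worm's central-frame
centroid (nearest first, id tie-break, warning past K). Decoding inverts the
encoding for slots above confidence 0.5; duplicates across cells are removed
by greedy non-maximum suppression on orientation-minimised mean point
distance (default radius 12 px).

The tiny reference predictor pools the 11-frame stack into three channels
(temporal mean, central frame, darkest projection), feeds a 32 px patch per
cell through one strided patch-linear layer (equivalent to a single stride-16
convolution) with ReLU and 64 hidden units, and emits confidence, per-frame
centroid offsets, translation-invariant shape coefficients, and the latent
vector; offsets and shape are recombined into standard cell-centre
coefficients exactly at prediction time. The loss is confidence binary
cross-entropy + masked MSE on the coefficient targets + a latent-consistency
term pulling latents of the same worm in overlapping cells together;
optimisation is full-batch Adam at learning rate 1e-3, seeded and exactly
reproducible. The confidence bias starts at −2 so an untrained model predicts
nothing. Mirror augmentation (×4) is on by default because the scene
statistics are mirror symmetric. At the 64 × 64 desk scale, worm length is
~26 px and the assignment cutoff is 16 px — the same worm-relative radius as
48 px at the full-scale 80 px worms (0.6 L). Detection recall counts a
ground-truth worm as found when a deduplicated detection above confidence 0.5
lies within 0.25 worm lengths in orientation-minimised mean point distance;
the 0.8 recall bar is an implementer-set contract, fixed before measurement.

### Temporal downsampling and splines (module `temporal_spline`)

Inference-time videos are thinned 1:3; each skeleton point's x(t) and y(t)
are then fitted with cubic smoothing splines sharing one smoothing parameter
(the median of GCV-selected values over six representative traces) and
evaluated at the skipped frames; outputs are re-normalised to equal spacing.
"3D" is interpreted as (x, y, t) — the simplest construction consistent with
a three-dimensional spline over planar skeletons. No extrapolation: targets
outside the observed range are an error, and gaps are the tracker's problem,
not the spline's. Linear motion is reproduced exactly at any smoothing
(the roughness penalty vanishes on linear functions), and the residual at
observed frames is non-decreasing in the smoothing parameter.

### Tracking (module `tracker`)

Frame-to-frame linking solves an optimal assignment (an O(n³) augmenting-path
Hungarian solver, tested against permutation enumeration) under
`cost = w_spatial × mean skeleton distance + w_latent × latent distance`,
with pairs beyond 3 worm lengths forbidden, new tracks for unmatched
detections, and gaps up to 12 frames bridged. The ablation baseline is
greedy centroid nearest-neighbour matching with no latent term and no gap
bridging. On the collinear-overtake fixture the spatial assignment costs tie
exactly; latents are what carries identity through, and the greedy baseline
demonstrably swaps.

### Evaluation (module `evaluation`)

RMSD resamples both skeletons to equal spacing and pairs points index to
index after head-tail alignment (orientation minimising the value when head
labels are absent — our reading of "minimum distances"). The nearest-segment
distance projects each predicted point onto the truth polyline, is asymmetric
by construction, and never exceeds the paired RMSD. Failure rules per
method: confidence-grid trackers fail with no skeleton above 0.5;
part-affinity-field outputs fail below 14 linked landmarks; contour trackers
(and mask-based trackers skeletonised the same way) require exactly two
supra-threshold contour-curvature points and a bounded max/min width ratio —
the curvature threshold and width bound are configurable because the
reference values are unpublished (defaults 0.5 and 2). Tracking fidelity is
`1 − Σ mme_t / Σ g_t` with `mme_t` counted per frame against the predicted
identity matched at each worm's first appearance; unmatched ground-truth
worms count as mismatches because their identity is not maintained. This
per-frame persistent-identity reading (rather than event counting) follows
from the "fraction of objects in each time step" phrasing.

### Screen statistics (module `screen_stats`)

Exemplar features only: median midbody speed (centroid of the middle third,
px/s) and median absolute tail curvature (finite differences along
arclength, 1/px). Pearson correlations per feature over pairwise-complete
matched wells (undefined below 3 pairs, flagged and excluded); the modal r
comes from a fixed 0.05-wide histogram on [−1, 1] because no binning is
published — kernel modes were considered and rejected as adding a bandwidth
choice with no reference value. One-way F is the between/within mean-square
ratio with F = 0 at exactly equal group means and +Inf at zero within-group
variance. Hedge's d is Cohen's d times J = 1 − 3/(4(n_t + n_c) − 9);
per-dose effects against pooled vehicle controls are converted to absolute
values and averaged across doses.

## Numerical and degenerate-input choices

- Equal-spacing resampling is linear along the polyline; endpoints are
  preserved and spacing is uniform to 1e−6 relative.
- Orientation ties (palindromic skeletons) keep the input orientation.
- Assignment costs ≥ 1e9 mark forbidden pairs; solver output for such pairs
  is reported as unmatched.
- Zero pooled variance makes Hedge's d NaN with a warning, never an error;
  an all-equal-means table gives F exactly 0.
- Empty scenes: zero worms render the background bit-for-bit; empty
  detection lists produce empty trajectory lists; an empty ground truth is
  an error for fidelity (the metric is undefined).

## File formats

The environment provides no HDF5/TIFF bindings for R, so stacks are RDS or a
plain-text `nematrack-stack` format, tables are CSV written at %.17g (the
round trip is lossless), shape spaces and configs are JSON. Every text table
carries a header comment stating the coordinate convention (0-based,
x = column, y = row, origin top-left).

## Known limitations

- The reference predictor is a contract exerciser, not a detector; its
  recall bar holds on simulator statistics only.
- Dense aggregates, mating pairs, and moving lawns are out of scope, as is
  any dynamic-background model.
- The spline stage splits rather than bridges long gaps (default > 25
  frames); adaptive temporal sampling is not attempted.
- Real-data headline numbers (median RMSD on annotated frames, failure
  counts, the modal feature correlation of a specific screen) require the
  original test data and full-scale trained models and are deliberately not
  asserted anywhere in this package.
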