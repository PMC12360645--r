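Package: nematrack
Title: Posture Tracking and Phenotypic-Screen Statistics for Crawling C. elegans
Version: 0.1.0
Authors@R: person("Nematrack", "Developers", email = "nematrack@example.org",
    role = c("aut", "cre"))
Description: A testable toolkit for multi-worm posture tracking in brightfield
    video: a synthetic crawling-worm video generator with ground-truth midlines
    (including overlap synthesis by stacking single-worm clips), rank-1 SVD
    background subtraction, an eigenworm PCA shape space with grid-cell
    (YOLO-style) prediction encoding and decoding, temporal downsampling with
    smoothing-spline interpolation, identity-preserving trajectory linking with
    a nearest-neighbour baseline, skeleton evaluation metrics (head-tail
    aligned RMSD, nearest-segment distance, per-method failure rules, tracking
    fidelity), and phenotypic-screen statistics (Pearson feature correlation,
    one-way F-statistic, Hedge's d effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
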