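test_that("skeleton RMSD: identity, translation, orientation minimisation", {
  s <- straight_skeleton(50, 50, len = 30, n = 11L)
  expect_equal(skeleton_rmsd(s, s), 0)
  shifted <- as_skeleton(unclass(s) + matrix(c(0, 3), 11L, 2L, byrow = TRUE))
  expect_equal(skeleton_rmsd(shifted, s), 3.0, tolerance = 1e-12)
  # reversal is absorbed by the head-tail alignment
  expect_equal(skeleton_rmsd(flip_skeleton(s), s), 0, tolerance = 1e-12)
  expect_gt(skeleton_rmsd(flip_skeleton(s), s, use_heads = TRUE), 0)
})

test_that("rmsd and nearest-segment distance match brute-force oracles", {
  set.seed(91)
  for (trial in 1:100) {
    n <- sample(5:12, 1L)
    p <- unclass(resample_equal_arclength(random_skeleton(n), n))
    t_ <- unclass(resample_equal_arclength(random_skeleton(n), n))
    expect_equal(skeleton_rmsd(p, t_, n = n), oracle_rmsd(p, t_),
                 tolerance = 1e-8)
    expect_equal(nearest_segment_distance(p, t_), oracle_segment_distance(p, t_),
                 tolerance = 1e-8)
  }
})

test_that("nearest-segment distance: overshoot geometry and asymmetry", {
  truth <- as_skeleton(cbind(x = c(0, 10, 20), y = c(0, 0, 0)))
  # prediction overshoots the end by 5 px along the same line
  pred <- as_skeleton(cbind(x = c(5, 15, 25), y = c(0, 0, 0)))
  # hand geometry: points at 5 and 15 lie on the polyline (0), point at 25
  # maps to the endpoint (20,0) at distance 5 -> mean 5/3
  expect_equal(nearest_segment_distance(pred, truth), 5 / 3, tolerance = 1e-12)
  expect_lt(nearest_segment_distance(pred, truth), skeleton_rmsd(pred, truth))
  # asymmetric: a longer overshooting prediction sees distances 0,0,5,15
  # (mean 5) while the truth against it only sees its own start overshoot
  pred2 <- as_skeleton(cbind(x = c(5, 15, 25, 35), y = c(0, 0, 0, 0)))
  expect_equal(nearest_segment_distance(pred2, truth), 5, tolerance = 1e-12)
  expect_equal(nearest_segment_distance(truth, pred2), 5 / 3, tolerance = 1e-12)
  expect_error(nearest_segment_distance(pred, cbind(1, 1)), "2 points")
})

test_that("per-method failure rules", {
  expect_equal(classify_failure("dtc", list(confidences = c(0.2, 0.49)))$status,
               "failed")
  expect_equal(classify_failure("dtc", list(confidences = numeric(0)))$status,
               "failed")
  expect_equal(classify_failure("dtc", list(confidences = c(0.51)))$status, "ok")

  expect_equal(classify_failure("paf", list(n_points = 13L))$status, "failed")
  expect_equal(classify_failure("paf", list(n_points = 14L))$status, "ok")

  good <- list(n_high_curvature_points = 2L, width_max = 4, width_min = 3)
  expect_equal(classify_failure("tierpsy", good)$status, "ok")
  expect_equal(classify_failure("omnipose", good)$status, "ok")
  coiled <- list(n_high_curvature_points = 4L, width_max = 4, width_min = 3)
  expect_equal(classify_failure("tierpsy", coiled)$status, "failed")
  fat <- list(n_high_curvature_points = 2L, width_max = 9, width_min = 3)
  expect_equal(classify_failure("tierpsy", fat)$status, "failed")
  # raw contour curvatures against the configurable threshold
  curv <- list(contour_curvature = c(0.1, 0.9, 0.05, -0.8, 0.2),
               width_max = 4, width_min = 3)
  expect_equal(classify_failure("tierpsy", curv)$status, "ok")

  expect_error(classify_failure("slic", list()), "arg")
})

test_that("tracking fidelity reproduces the hand-counted swap example", {
  # 2 worms x 10 frames, identities swapped from frame 6 onward
  truth <- list(
    A = skeleton_series(1:10, lapply(1:10, function(f) straight_skeleton(10 * f, 0)), "A"),
    B = skeleton_series(1:10, lapply(1:10, function(f) straight_skeleton(10 * f, 60)), "B"))
  mk_traj <- function(id, frames, sks) {
    tr <- list(worm_id = id, frames = frames, skeletons = sks,
               confidences = rep(1, length(frames)), latents = vector("list", length(frames)))
    class(tr) <- "worm_trajectory"
    tr
  }
  p1 <- mk_traj("p1", 1:10, lapply(1:10, function(f)
    if (f <= 5) straight_skeleton(10 * f, 0) else straight_skeleton(10 * f, 60)))
  p2 <- mk_traj("p2", 1:10, lapply(1:10, function(f)
    if (f <= 5) straight_skeleton(10 * f, 60) else straight_skeleton(10 * f, 0)))
  res <- tracking_fidelity(list(p1, p2), truth)
  expect_equal(sum(res$g), 20L)
  expect_equal(sum(res$mme), 10L)     # 2 mismatches x 5 frames
  expect_equal(res$fidelity, 0.5)

  # perfect tracks give 1
  perfect <- list(
    mk_traj("q1", 1:10, truth$A$skeletons),
    mk_traj("q2", 1:10, truth$B$skeletons))
  expect_equal(tracking_fidelity(perfect, truth)$fidelity, 1.0)
  expect_error(tracking_fidelity(perfect, list()), "empty")
})

test_that("fidelity matches the brute-force oracle on random small scenarios", {
  set.seed(55)
  for (trial in 1:25) {
    n_worms <- sample(2:4, 1L)
    n_frames <- sample(8:20, 1L)
    base_y <- seq(0, by = 50, length.out = n_worms)
    truth <- lapply(seq_len(n_worms), function(w)
      skeleton_series(seq_len(n_frames), lapply(seq_len(n_frames), function(f)
        straight_skeleton(5 * f + runif(1, -1, 1), base_y[w])), paste0("w", w)))
    names(truth) <- paste0("w", seq_len(n_worms))
    # predicted tracks: random identity shuffles at a random frame
    swap_at <- sample(2:n_frames, 1L)
    perm <- sample(n_worms)
    preds <- lapply(seq_len(n_worms), function(w) {
      sks <- lapply(seq_len(n_frames), function(f) {
        src <- if (f < swap_at) w else perm[w]
        truth[[src]]$skeletons[[f]]
      })
      tr <- list(worm_id = paste0("p", w), frames = seq_len(n_frames),
                 skeletons = sks, confidences = rep(1, n_frames),
                 latents = vector("list", n_frames))
      class(tr) <- "worm_trajectory"
      tr
    })
    got <- tracking_fidelity(preds, truth, gate = 10)
    want <- oracle_fidelity(preds, truth, gate = 10)
    expect_equal(got$fidelity, want, tolerance = 1e-8)
    expect_true(got$fidelity >= 0 && got$fidelity <= 1)
    expect_true(all(got$mme <= got$g))
  }
})
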