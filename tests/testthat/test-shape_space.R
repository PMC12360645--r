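test_that("equal-arclength resampling is uniform, idempotent, length-preserving", {
  # straight vertical segment: points at integer y
  line <- as_skeleton(cbind(x = c(0, 0), y = c(0, 48)))
  rs <- resample_equal_arclength(line, 49L)
  expect_equal(unclass(rs), cbind(x = rep(0, 49), y = 0:48), tolerance = 1e-12,
               ignore_attr = TRUE)

  # idempotence on an already-uniform skeleton
  rs2 <- resample_equal_arclength(rs, 49L)
  expect_lt(max(abs(unclass(rs2) - unclass(rs))), 1e-9)

  # quarter circle: uniform spacing, arclength preserved vs dense integration
  th <- seq(0, pi / 2, length.out = 2001L)
  arc <- cbind(x = 30 * cos(th), y = 30 * sin(th))
  dense_len <- sum(sqrt(rowSums(diff(arc)^2)))   # numerical arclength oracle
  rs3 <- resample_equal_arclength(arc, 25L)
  seg <- sqrt(rowSums(diff(unclass(rs3))^2))
  expect_lt((max(seg) - min(seg)) / mean(seg), 1e-6)
  expect_lt(abs(skeleton_arclength(rs3) - dense_len) / dense_len, 1e-3)

  expect_error(resample_equal_arclength(cbind(0, 0)), "2 points")
})

test_that("head-tail orientation follows the reference and breaks ties to no-flip", {
  set.seed(11)
  s <- random_skeleton(15L)
  expect_identical(orient_head_tail(s, reference_skeleton = s), s)
  flipped <- flip_skeleton(s)
  expect_equal(unclass(orient_head_tail(flipped, reference_skeleton = s)),
               unclass(s))
  # symmetric shape: tie kept as-is
  sym <- as_skeleton(cbind(x = -3:3, y = rep(0, 7)))
  expect_identical(orient_head_tail(sym, reference_skeleton = sym), sym)
})

test_that("generator head leads the motion in forward frames", {
  rec <- single_worm_recording()
  frames <- seq_along(rec$skeletons)
  lead <- vapply(frames[-1L], function(f) {
    cur <- unclass(rec$skeletons[[f]][[1L]])
    prev <- unclass(rec$skeletons[[f - 1L]][[1L]])
    v <- colMeans(cur) - colMeans(prev)
    if (sqrt(sum(v^2)) < 0.2) return(NA)  # dwelling: no direction
    head_d <- sum((cur[1L, ] - colMeans(cur)) * v)
    tail_d <- sum((cur[nrow(cur), ] - colMeans(cur)) * v)
    head_d > tail_d
  }, logical(1L))
  expect_gt(mean(lead, na.rm = TRUE), 0.9)
  # and the motion-based orientation recovers the labelled head
  sks <- lapply(frames, function(f) rec$skeletons[[f]][[1L]])
  oriented <- orient_track_by_motion(lapply(sks, flip_skeleton))
  expect_equal(unclass(oriented[[10L]]), unclass(sks[[10L]]))
})

test_that("PCA shape space: ordering, dimensions, degenerate input", {
  rec <- tiny_recording()
  sks <- lapply(unlist(rec$skeletons, recursive = FALSE),
                resample_equal_arclength, n = 49L)
  space <- fit_shape_space(sks, D = 72L)
  expect_equal(dim(space$basis), c(72L, 98L))
  expect_lt(max(abs(space$basis %*% t(space$basis) - diag(72L))), 1e-8)
  expect_true(all(diff(space$sdev[1:72]) <= 1e-9))

  expect_error(fit_shape_space(sks, D = 99L), "2N")
  expect_error(fit_shape_space(sks[1:10], D = 72L), "at least")

  # identical skeletons: mean equals the shape, coefficients vanish
  same <- rep(list(sks[[1L]]), 30L)
  sp0 <- fit_shape_space(same, D = 4L)
  expect_equal(sp0$mean, c(unclass(sks[[1L]])[, 1L], unclass(sks[[1L]])[, 2L]),
               tolerance = 1e-10)
  expect_equal(encode_skeleton(sks[[1L]], sp0), rep(0, 4L), tolerance = 1e-8)
})

test_that("reconstruction error is monotone in D and exact at D = 2N", {
  rec <- tiny_recording()
  sks <- lapply(unlist(rec$skeletons, recursive = FALSE),
                resample_equal_arclength, n = 25L)
  train <- sks[seq_along(sks) %% 2L == 1L]
  test <- sks[seq_along(sks) %% 2L == 0L][1:20]
  recon_rmsd <- function(D) {
    sp <- fit_shape_space(train, D = D)
    mean(vapply(test, function(s)
      skeleton_rmsd(decode_skeleton(encode_skeleton(s, sp), sp), s,
                    use_heads = TRUE), numeric(1L)))
  }
  e12 <- recon_rmsd(12L); e40 <- recon_rmsd(40L); e50 <- recon_rmsd(50L)
  expect_lte(e40, e12 + 1e-12)
  expect_lte(e50, e40 + 1e-12)
  sp_full <- fit_shape_space(train, D = 50L)
  s <- test[[1L]]
  expect_lt(skeleton_rmsd(decode_skeleton(encode_skeleton(s, sp_full), sp_full),
                          s, use_heads = TRUE), 1e-9)
})

test_that("encode/decode: offsets, linearity, error cases", {
  sp <- tiny_shape_space()
  rec <- tiny_recording()
  s <- resample_equal_arclength(rec$skeletons[[5L]][[1L]], 25L)
  off <- c(123.5, 77.5)
  # at full rank the reference origin is immaterial: exact round trip either way
  sks <- lapply(unlist(rec$skeletons, recursive = FALSE),
                resample_equal_arclength, n = 25L)
  sp_full <- fit_shape_space(sks, D = 50L)
  rt <- decode_skeleton(encode_skeleton(s, sp_full, off), sp_full, off)
  expect_equal(unclass(rt), unclass(s), tolerance = 1e-9, ignore_attr = TRUE)
  # at truncated D the difference is bounded by the out-of-span translation
  rt_t <- decode_skeleton(encode_skeleton(s, sp, off), sp, off)
  rt_0 <- decode_skeleton(encode_skeleton(s, sp), sp)
  tv <- c(rep(off[1L], sp$N), rep(off[2L], sp$N))
  bound <- sqrt(sum((tv - drop(crossprod(sp$basis, sp$basis %*% tv)))^2))
  expect_lte(sqrt(sum((unclass(rt_t) - unclass(rt_0))^2)), bound + 1e-9)

  # mean shape encodes to zero
  N <- sp$N
  mean_sk <- as_skeleton(cbind(x = sp$mean[1:N], y = sp$mean[(N + 1L):(2L * N)]))
  expect_equal(encode_skeleton(mean_sk, sp), rep(0, sp$D), tolerance = 1e-10)

  # linearity of encoding in the skeleton
  s2 <- resample_equal_arclength(rec$skeletons[[40L]][[2L]], 25L)
  a <- 0.3
  blend <- as_skeleton(a * unclass(s) + (1 - a) * unclass(s2))
  expect_equal(encode_skeleton(blend, sp),
               a * encode_skeleton(s, sp) + (1 - a) * encode_skeleton(s2, sp),
               tolerance = 1e-9)

  expect_error(decode_skeleton(rep(0, sp$D + 1L), sp), "match D")
  expect_error(encode_skeleton(resample_equal_arclength(s, 10L), sp), "match")
})
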