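# Temporal downsampling and smoothing-spline interpolation. Inference is run
# on every third frame only; each skeleton point is then traced through time
# as two coupled 1-D cubic smoothing splines (x(t), y(t)) with one shared
# smoothing parameter, and the skipped frames are filled in by evaluating the
# splines. Interpolated skeletons are re-normalised to equal arclength
# spacing.

#' Keep every k-th frame index
#'
#' @param frame_indices integer vector of frame indices.
#' @param k downsampling factor (default 3).
#' @return the kept indices (every k-th starting at the first).
#' @export
downsample_frames <- function(frame_indices, k = 3L) {
  if (k < 1L) stop("k must be >= 1")
  frame_indices[seq(1L, length(frame_indices), by = k)]
}

#' Construct a skeleton time series
#' @param frames strictly increasing integer frame indices.
#' @param skeletons list of N x 2 skeletons, one per frame, same N.
#' @param worm_id identifier.
#' @return `skeleton_series` object.
#' @export
skeleton_series <- function(frames, skeletons, worm_id = "w01") {
  if (length(frames) != length(skeletons)) stop("frames/skeletons length mismatch")
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  N <- nrow(skeletons[[1L]])
  if (any(vapply(skeletons, nrow, integer(1L)) != N))
    stop("skeletons must share point count")
  structure(list(frames = as.integer(frames), skeletons = skeletons,
                 worm_id = worm_id, N = N),
            class = "skeleton_series")
}

#' Interpolate a skeleton time series with smoothing splines
#'
#' Fits cubic smoothing splines in time to every skeleton point coordinate
#' with one shared smoothing parameter and evaluates them at `target_frames`.
#' With `smoothing = "gcv"` the shared parameter is the median of the
#' GCV-selected parameters over a subset of representative point traces; a
#' numeric `smoothing` is passed through as `spar` (0 = near interpolation,
#' larger = smoother). No extrapolation: targets outside the observed range
#' are an error.
#'
#' @param series a `skeleton_series` with at least 4 frames.
#' @param target_frames frames at which skeletons are wanted.
#' @param smoothing "gcv" (default) or a numeric `spar`.
#' @return a `skeleton_series` over `target_frames`, equal-spacing normalised.
#' @export
interpolate_spline <- function(series, target_frames, smoothing = "gcv") {
  fr <- series$frames
  if (length(fr) < 4L) stop("need at least 4 observed frames to fit a spline")
  target_frames <- as.integer(target_frames)
  if (min(target_frames) < fr[1L] || max(target_frames) > fr[length(fr)])
    stop("extrapolation outside the observed frame range is not supported")
  N <- series$N
  # coordinate traces: one column per (point, coord)
  tr <- matrix(0, length(fr), 2L * N)
  for (i in seq_along(fr)) {
    s <- unclass(series$skeletons[[i]])
    tr[i, ] <- c(s[, 1L], s[, 2L])
  }
  spar <- if (identical(smoothing, "gcv")) {
    probe <- unique(c(1L, N %/% 2L + 1L, N, N + 1L, N + N %/% 2L + 1L, 2L * N))
    sp <- vapply(probe, function(j) {
      f <- try(stats::smooth.spline(fr, tr[, j], cv = FALSE), silent = TRUE)
      if (inherits(f, "try-error")) NA_real_ else f$spar
    }, numeric(1L))
    sp <- sp[is.finite(sp)]
    if (length(sp) == 0L) 0.5 else stats::median(sp)
  } else as.numeric(smoothing)
  fits <- lapply(seq_len(2L * N), function(j)
    stats::smooth.spline(fr, tr[, j], spar = spar, cv = FALSE))
  pred <- vapply(fits, function(f) stats::predict(f, target_frames)$y,
                 numeric(length(target_frames)))
  pred <- matrix(pred, nrow = length(target_frames))
  out <- lapply(seq_along(target_frames), function(i) {
    resample_equal_arclength(cbind(x = pred[i, 1:N],
                                   y = pred[i, (N + 1L):(2L * N)]), N)
  })
  skeleton_series(target_frames, out, series$worm_id)
}

#' Residual sum of squares of a spline fit at the observed frames
#'
#' Helper for smoothing diagnostics: total squared residual of the shared-spar
#' spline fit at the observed frames of a series.
#'
#' @param series a `skeleton_series`.
#' @param spar smoothing parameter.
#' @return scalar residual sum of squares.
#' @export
spline_observed_rss <- function(series, spar) {
  fr <- series$frames
  N <- series$N
  rss <- 0
  for (j in seq_len(2L * N)) {
    y <- vapply(seq_along(fr), function(i) {
      s <- unclass(series$skeletons[[i]])
      if (j <= N) s[j, 1L] else s[j - N, 2L]
    }, numeric(1L))
    f <- stats::smooth.spline(fr, y, spar = spar, cv = FALSE)
    rss <- rss + sum((stats::predict(f, fr)$y - y)^2)
  }
  rss
}
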