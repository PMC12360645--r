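# Rank-1 SVD background model. Frames are temporally subsampled (1:400 by
# default), arranged as a (pixels x sampled frames) matrix, and the highest
# energy singular triplet is taken as the background: for long recordings of
# crawling worms the first mode is the static background, because worms are
# sparse and move between the widely spaced sampled frames.

#' Estimate a static background by rank-1 SVD
#'
#' @param video H x W x T array of frames.
#' @param subsample_step temporal subsampling step (default 400); when the
#'   video is shorter than one step, all frames are used.
#' @return `background_model`: list with `image` (H x W), `n_frames_used`,
#'   `subsample_step`.
#' @details The unit-norm spatial singular vector is rescaled by the singular
#'   value times the mean temporal coefficient so the image lives in intensity
#'   units; the SVD sign ambiguity is resolved by forcing a non-negative mean
#'   on the spatial mode. For a perfectly static video the estimate equals any
#'   frame to machine precision.
#' @export
estimate_background <- function(video, subsample_step = 400L) {
  d <- dim(video)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L)
    stop("video must be a non-empty H x W x T array")
  step <- max(1L, as.integer(subsample_step))
  # shorter than one step: degenerate-input fallback, use every frame
  idx <- if (d[3L] <= step) seq_len(d[3L]) else seq(1L, d[3L], by = step)
  M <- matrix(video[, , idx, drop = FALSE], nrow = d[1L] * d[2L])
  sv <- svd(M, nu = 1L, nv = 1L)
  mode1 <- sv$u[, 1L] * sv$d[1L] * mean(sv$v[, 1L])
  if (mean(mode1) < 0) mode1 <- -mode1
  structure(list(image = matrix(mode1, d[1L], d[2L]),
                 n_frames_used = length(idx),
                 subsample_step = as.integer(subsample_step)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: %d x %d px from %d frames (step %d)\n",
              nrow(x$image), ncol(x$image), x$n_frames_used, x$subsample_step))
  invisible(x)
}

#' Subtract an estimated background from every frame
#'
#' @param video H x W x T array.
#' @param model a `background_model` (or a bare H x W matrix).
#' @return H x W x T residual array (frame minus background).
#' @export
subtract_background <- function(video, model) {
  img <- if (inherits(model, "background_model")) model$image else model
  d <- dim(video)
  if (is.null(d) || length(d) != 3L) stop("video must be an H x W x T array")
  if (!identical(d[1:2], dim(img)))
    stop("background shape does not match frame shape")
  sweep(video, c(1L, 2L), img)
}
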