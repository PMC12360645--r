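# Eigenworm shape space: skeletons, normalised to equal arclength spacing and
# head-tail oriented, are flattened to length-2N vectors c(x, y) and embedded
# in a D-dimensional PCA basis. Grid-cell detections are stored as the D
# coefficients of the skeleton *relative to the predicting cell's centre*, so
# the space itself is translation invariant.

#' Fit a PCA shape space on a set of skeletons
#'
#' Skeletons must share the same point count N and be normalised (equal
#' spacing, consistent head-tail orientation). Each skeleton contributes one
#' length-2N observation vector `c(x, y)`; the space holds the mean shape and
#' the top `D` principal axes as orthonormal rows, ordered by decreasing
#' explained variance. `D = 2N` gives exact reconstruction.
#'
#' @param skeletons list of N x 2 skeleton matrices.
#' @param D number of retained components (default 72).
#' @return An object of class `shape_space`: list with `mean` (length 2N),
#'   `basis` (D x 2N, orthonormal rows), `sdev` (singular values / sqrt(n-1)),
#'   `N`, `D`.
#' @export
fit_shape_space <- function(skeletons, D = 72L) {
  if (length(skeletons) < 1L) stop("no skeletons supplied")
  N <- nrow(skeletons[[1L]])
  if (D > 2L * N) stop("D cannot exceed 2N")
  if (length(skeletons) < D)
    stop(sprintf("need at least D = %d skeletons, got %d", D, length(skeletons)))
  X <- t(vapply(skeletons, function(s) {
    s <- unclass(as.matrix(s))
    if (nrow(s) != N) stop("skeletons differ in point count")
    c(s[, 1L], s[, 2L])
  }, numeric(2L * N)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = min(nrow(Xc), ncol(Xc)))
  if (ncol(sv$v) < D) stop("not enough independent skeletons for requested D")
  basis <- t(sv$v[, seq_len(D), drop = FALSE])
  structure(list(mean = mu, basis = basis,
                 sdev = sv$d / sqrt(max(nrow(X) - 1L, 1L)),
                 N = N, D = as.integer(D)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: N = %d points, D = %d components\n", x$N, x$D))
  invisible(x)
}

#' Encode a skeleton as shape-space coefficients
#'
#' @param skeleton N x 2 matrix, normalised.
#' @param space a `shape_space`.
#' @param offset length-2 reference origin (e.g. the predicting grid cell's
#'   centre) subtracted from the coordinates before projection.
#' @return length-D coefficient vector.
#' @export
encode_skeleton <- function(skeleton, space, offset = c(0, 0)) {
  s <- unclass(as.matrix(skeleton))
  if (nrow(s) != space$N) stop("skeleton point count does not match shape space")
  v <- c(s[, 1L] - offset[1L], s[, 2L] - offset[2L]) - space$mean
  drop(space$basis %*% v)
}

#' Decode shape-space coefficients back to a skeleton
#'
#' @param coeffs length-D coefficient vector.
#' @param space a `shape_space`.
#' @param offset length-2 origin re-added after reconstruction.
#' @return N x 2 skeleton.
#' @export
decode_skeleton <- function(coeffs, space, offset = c(0, 0)) {
  if (length(coeffs) != space$D) stop("coefficient length does not match D")
  v <- space$mean + drop(crossprod(space$basis, coeffs))
  N <- space$N
  as_skeleton(cbind(x = v[1:N] + offset[1L], y = v[(N + 1L):(2L * N)] + offset[2L]))
}

#' Orient a whole skeleton track by motion
#'
#' Chooses, for an entire track at once, the head-tail orientation under which
#' the leading endpoint travels furthest: the end with the larger total
#' displacement along the direction of motion is called the head. Returns the
#' series with every skeleton flipped or not as a block (orientation is
#' consistent across frames by construction).
#'
#' @param skeletons list of N x 2 skeletons, one per frame, consistent
#'   internal ordering.
#' @return list of skeletons, possibly all reversed.
#' @export
orient_track_by_motion <- function(skeletons) {
  if (length(skeletons) < 2L) return(skeletons)
  lead_a <- 0; lead_b <- 0
  for (t in 2:length(skeletons)) {
    prev <- unclass(skeletons[[t - 1L]]); cur <- unclass(skeletons[[t]])
    v <- colMeans(cur) - colMeans(prev)
    if (sqrt(sum(v^2)) < .Machine$double.eps) next
    ctr <- colMeans(cur)
    lead_a <- lead_a + sum((cur[1L, ] - ctr) * v)
    lead_b <- lead_b + sum((cur[nrow(cur), ] - ctr) * v)
  }
  if (lead_b > lead_a) lapply(skeletons, flip_skeleton) else skeletons
}
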