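# Coordinate convention used throughout: 0-based pixel coordinates,
# x = column, y = row, origin at the top-left of the frame. A skeleton is an
# N x 2 numeric matrix (columns x, y), first row = head, last row = tail.

#' Validate a skeleton matrix
#'
#' A skeleton is an ordered midline: an N x 2 numeric matrix of pixel
#' coordinates with the head first. Consecutive points must be distinct and
#' all coordinates finite.
#'
#' @param points N x 2 numeric matrix (columns x, y).
#' @return The validated matrix, invisibly classed as `worm_skeleton`.
#' @export
as_skeleton <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("a skeleton needs an N x 2 matrix with N >= 2")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("skeleton has non-finite coordinates")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("skeleton has coincident consecutive points")
  class(points) <- c("worm_skeleton", "matrix", "array")
  points
}

#' Polyline arclength of a skeleton
#' @param points skeleton matrix.
#' @return Total arclength in pixels.
#' @export
skeleton_arclength <- function(points) {
  d <- diff(unclass(points))
  sum(sqrt(rowSums(d^2)))
}

#' Resample a skeleton to equal arclength spacing
#'
#' Linearly interpolates along the polyline so that the `n` output points are
#' separated by equal arclength steps; endpoints are preserved. This is the
#' normalisation applied before PCA encoding and before RMSD computation.
#'
#' @param points skeleton matrix (>= 2 distinct points).
#' @param n number of output points (default 49).
#' @return An `n` x 2 skeleton.
#' @export
resample_equal_arclength <- function(points, n = 49L) {
  points <- unclass(as.matrix(points))
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) stop("zero-length skeleton cannot be resampled")
  target <- seq(0, total, length.out = n)
  x <- stats::approx(s, points[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, points[, 2L], xout = target, ties = "ordered")$y
  out <- cbind(x = x, y = y)
  # guard against duplicate interior points from degenerate input
  as_skeleton(out)
}

#' Reverse a skeleton head-to-tail
#' @param points skeleton matrix.
#' @export
flip_skeleton <- function(points) {
  as_skeleton(unclass(points)[rev(seq_len(nrow(points))), , drop = FALSE])
}

# index-to-index root mean squared point distance (no alignment)
point_rmsd <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (nrow(a) != nrow(b)) stop("skeletons differ in point count")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Orient a skeleton so the head leads
#'
#' With a reference skeleton, returns the orientation (as-is or reversed)
#' minimising the index-to-index RMSD to the reference; exact ties keep the
#' input orientation. With a reference motion vector (displacement of the worm
#' between frames), picks the orientation whose first point is the endpoint
#' furthest along the direction of motion, mirroring the motion heuristic of
#' classical head-tail assignment.
#'
#' @param points skeleton matrix.
#' @param reference_skeleton optional skeleton with known orientation.
#' @param reference_motion optional length-2 displacement vector (dx, dy).
#' @return Oriented skeleton.
#' @export
orient_head_tail <- function(points, reference_skeleton = NULL,
                             reference_motion = NULL) {
  points <- as_skeleton(points)
  if (!is.null(reference_skeleton)) {
    fwd <- point_rmsd(points, reference_skeleton)
    rev_ <- point_rmsd(flip_skeleton(points), reference_skeleton)
    if (rev_ < fwd) return(flip_skeleton(points))
    return(points)
  }
  if (!is.null(reference_motion)) {
    v <- as.numeric(reference_motion)
    ctr <- colMeans(unclass(points))
    lead_head <- sum((unclass(points)[1L, ] - ctr) * v)
    lead_tail <- sum((unclass(points)[nrow(points), ] - ctr) * v)
    if (lead_tail > lead_head) return(flip_skeleton(points))
    return(points)
  }
  points
}

#' Signed curvature along a skeleton
#'
#' Finite-difference curvature (1/px) at each interior point of an
#' equally spaced skeleton; endpoints are copied from their neighbours.
#'
#' @param points skeleton matrix, assumed approximately equally spaced.
#' @return numeric vector of length N.
#' @export
skeleton_curvature <- function(points) {
  p <- unclass(as.matrix(points))
  n <- nrow(p)
  if (n < 3L) return(rep(0, n))
  d1 <- (p[3:n, ] - p[1:(n - 2L), ]) / 2
  d2 <- p[3:n, ] - 2 * p[2:(n - 1L), ] + p[1:(n - 2L), ]
  sp <- rowSums(d1^2)^1.5
  k <- (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) / pmax(sp, .Machine$double.eps)
  c(k[1L], k, k[length(k)])
}

skeleton_centroid <- function(points) colMeans(unclass(as.matrix(points)))
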