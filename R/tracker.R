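# Identity-preserving trajectory linking. Detections are matched frame to
# frame by optimal (Hungarian) assignment under a combined cost: spatial
# (orientation-minimised mean skeleton point distance) plus, optionally, the
# Euclidean distance between latent embeddings, which carries identity
# through collisions where geometry alone is ambiguous. A greedy centroid
# nearest-neighbour linker without latent term or gap bridging is provided as
# the ablation baseline.

new_trajectory <- function(worm_id) {
  structure(list(worm_id = worm_id, frames = integer(0), skeletons = list(),
                 confidences = numeric(0), latents = list()),
            class = "worm_trajectory")
}

traj_append <- function(tr, det) {
  tr$frames <- c(tr$frames, det$frame)
  tr$skeletons[[length(tr$skeletons) + 1L]] <- det$skeleton
  tr$confidences <- c(tr$confidences, det$confidence %||% NA_real_)
  tr$latents[[length(tr$latents) + 1L]] <- det$latent
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.worm_trajectory <- function(x, ...) {
  cat(sprintf("worm_trajectory %s: %d entries, frames %d..%d\n", x$worm_id,
              length(x$frames),
              if (length(x$frames)) min(x$frames) else NA,
              if (length(x$frames)) max(x$frames) else NA))
  invisible(x)
}

det_frames <- function(detections)
  vapply(detections, `[[`, numeric(1L), "frame")

#' Link detections into identity-preserving trajectories
#'
#' Processes frames in order; at each frame, open trajectories are matched to
#' the frame's detections by minimum-cost bipartite assignment with
#' cost = `w_spatial` x mean skeleton distance + `w_latent` x latent Euclidean
#' distance. Pairs whose spatial distance exceeds `gate` are forbidden.
#' Unmatched detections start new trajectories; trajectories unmatched for
#' more than `max_gap` frames are closed (gaps up to `max_gap` are bridged).
#'
#' @param detections list of detections: each a list with `frame`, `skeleton`,
#'   optional `confidence` and `latent`.
#' @param w_spatial spatial cost weight (default 1).
#' @param w_latent latent cost weight (default 1; set 0 to ignore latents).
#' @param max_gap largest bridged gap in frames (default 12).
#' @param gate forbidden-pair spatial distance; default 3 x the median
#'   skeleton arclength among the detections.
#' @return list of `worm_trajectory`.
#' @export
link_detections <- function(detections, w_spatial = 1, w_latent = 1,
                            max_gap = 12L, gate = NULL) {
  if (length(detections) == 0L) return(list())
  if (w_spatial < 0 || w_latent < 0) stop("weights must be >= 0")
  if (is.null(gate)) {
    lens <- vapply(detections, function(d) skeleton_arclength(d$skeleton),
                   numeric(1L))
    gate <- 3 * stats::median(lens)
  }
  fr <- det_frames(detections)
  open <- list()     # each: list(traj, last_frame, last_skel, last_latent)
  closed <- list()
  next_id <- 1L
  for (f in sort(unique(fr))) {
    # retire stale trajectories
    stale <- vapply(open, function(o) f - o$last_frame > max_gap, logical(1L))
    closed <- c(closed, lapply(open[stale], `[[`, "traj"))
    open <- open[!stale]
    dets <- detections[fr == f]
    if (length(open) > 0L && length(dets) > 0L) {
      cost <- matrix(BIG_COST, length(open), length(dets))
      for (i in seq_along(open)) for (j in seq_along(dets)) {
        sp <- mean_point_distance(open[[i]]$last_skel, dets[[j]]$skeleton)
        if (sp > gate) next
        lc <- 0
        if (w_latent > 0 && !is.null(open[[i]]$last_latent) &&
            !is.null(dets[[j]]$latent))
          lc <- sqrt(sum((open[[i]]$last_latent - dets[[j]]$latent)^2))
        cost[i, j] <- w_spatial * sp + w_latent * lc
      }
      match <- solve_assignment(cost)
      used <- rep(FALSE, length(dets))
      for (i in seq_along(open)) {
        j <- match[i]
        if (!is.na(j)) {
          open[[i]]$traj <- traj_append(open[[i]]$traj, dets[[j]])
          open[[i]]$last_frame <- f
          open[[i]]$last_skel <- dets[[j]]$skeleton
          open[[i]]$last_latent <- dets[[j]]$latent
          used[j] <- TRUE
        }
      }
      dets <- dets[!used]
    }
    for (d in dets) {
      tr <- traj_append(new_trajectory(sprintf("t%03d", next_id)), d)
      next_id <- next_id + 1L
      open[[length(open) + 1L]] <- list(traj = tr, last_frame = f,
                                        last_skel = d$skeleton,
                                        last_latent = d$latent)
    }
  }
  c(closed, lapply(open, `[[`, "traj"))
}

#' Greedy centroid nearest-neighbour linking (baseline)
#'
#' Frame-to-frame greedy matching on centroid distance only: pairs are taken
#' in order of increasing distance; no latent term, no gap bridging (a
#' trajectory not matched in the immediately following frame is closed).
#'
#' @param detections as for [link_detections()].
#' @return list of `worm_trajectory`.
#' @export
nearest_neighbour_link <- function(detections) {
  if (length(detections) == 0L) return(list())
  fr <- det_frames(detections)
  open <- list(); closed <- list(); next_id <- 1L
  for (f in sort(unique(fr))) {
    stale <- vapply(open, function(o) f - o$last_frame > 1L, logical(1L))
    closed <- c(closed, lapply(open[stale], `[[`, "traj"))
    open <- open[!stale]
    dets <- detections[fr == f]
    if (length(open) > 0L && length(dets) > 0L) {
      cen_o <- t(vapply(open, function(o) skeleton_centroid(o$last_skel),
                        numeric(2L)))
      cen_d <- t(vapply(dets, function(d) skeleton_centroid(d$skeleton),
                        numeric(2L)))
      dmat <- sqrt(outer(cen_o[, 1L], cen_d[, 1L], "-")^2 +
                   outer(cen_o[, 2L], cen_d[, 2L], "-")^2)
      dmat <- matrix(dmat, length(open), length(dets))
      used_o <- rep(FALSE, length(open)); used_d <- rep(FALSE, length(dets))
      repeat {
        dmat[used_o, ] <- Inf; dmat[, used_d] <- Inf
        if (all(!is.finite(dmat))) break
        k <- arrayInd(which.min(dmat), dim(dmat))
        i <- k[1L]; j <- k[2L]
        open[[i]]$traj <- traj_append(open[[i]]$traj, dets[[j]])
        open[[i]]$last_frame <- f
        open[[i]]$last_skel <- dets[[j]]$skeleton
        used_o[i] <- TRUE; used_d[j] <- TRUE
        if (all(used_o) || all(used_d)) break
      }
      dets <- dets[!used_d]
    }
    for (d in dets) {
      tr <- traj_append(new_trajectory(sprintf("t%03d", next_id)), d)
      next_id <- next_id + 1L
      open[[length(open) + 1L]] <- list(traj = tr, last_frame = f,
                                        last_skel = d$skeleton)
    }
  }
  c(closed, lapply(open, `[[`, "traj"))
}
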