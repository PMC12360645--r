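# Evaluation metrics: head-tail aligned point-to-point RMSD on equally spaced
# skeletons, nearest-segment midline distance, per-method failure rules, and
# the tracking fidelity 1 - sum(mme_t) / sum(g_t), where mme_t counts the
# ground-truth objects at frame t whose matched predicted track identity
# differs from the identity matched at their first appearance.

#' Root mean square deviation between two skeletons
#'
#' Both skeletons are resampled to `n` equally spaced points. With
#' `use_heads = TRUE` the stored orientation is trusted and points are paired
#' index to index; otherwise the orientation (as-is or reversed) minimising
#' the RMSD is used — the head-tail alignment applied when head labels are
#' unavailable.
#'
#' @param predicted,truth skeleton matrices.
#' @param n common resampling point count (default: the larger of the two).
#' @param use_heads trust the stored head-first orientation (default FALSE).
#' @return RMSD in px.
#' @export
skeleton_rmsd <- function(predicted, truth, n = NULL, use_heads = FALSE) {
  if (is.null(n)) n <- max(nrow(predicted), nrow(truth))
  p <- unclass(resample_equal_arclength(predicted, n))
  t_ <- unclass(resample_equal_arclength(truth, n))
  if (nrow(p) != nrow(t_)) stop("point counts differ after resampling")
  fwd <- sqrt(mean(rowSums((p - t_)^2)))
  if (use_heads) return(fwd)
  rev_ <- sqrt(mean(rowSums((p[rev(seq_len(n)), ] - t_)^2)))
  min(fwd, rev_)
}

# distance from one point to the segment ab
point_segment_distance <- function(pt, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t_ <- if (L2 == 0) 0 else max(0, min(1, sum((pt - a) * ab) / L2))
  sqrt(sum((a + t_ * ab - pt)^2))
}

#' Mean distance from predicted points to the nearest portion of the truth
#'
#' For every predicted point, the distance to the nearest point on the truth
#' polyline (projection onto segments, not vertex-only) is computed; the mean
#' over predicted points is returned. Asymmetric by construction: overshoot
#' beyond an endpoint maps to that endpoint.
#'
#' @param predicted skeleton whose points are measured.
#' @param truth reference polyline (>= 2 points).
#' @return mean nearest-segment distance in px.
#' @export
nearest_segment_distance <- function(predicted, truth) {
  p <- unclass(as.matrix(predicted)); t_ <- unclass(as.matrix(truth))
  if (nrow(t_) < 2L) stop("truth polyline needs at least 2 points")
  mean(vapply(seq_len(nrow(p)), function(i) {
    min(vapply(seq_len(nrow(t_) - 1L), function(j)
      point_segment_distance(p[i, ], t_[j, ], t_[j + 1L, ]), numeric(1L)))
  }, numeric(1L)))
}

#' Classify a raw tracker output as a failed prediction
#'
#' Applies the method-specific rule deciding whether a prediction was made at
#' all. Confidence-grid methods fail when no skeleton has confidence above
#' 0.5. Part-affinity-field outputs fail when fewer than 14 landmark points
#' were linked. Contour methods (tierpsy; omnipose uses the same rule since
#' its masks are skeletonised the same way) require exactly two
#' supra-threshold curvature points on the contour (head and tail) and a
#' bounded max/min width ratio, which rejects coiled shapes with a wrong
#' skeleton.
#'
#' @param method one of "tierpsy", "dtc", "paf", "omnipose".
#' @param raw_output named list. For dtc: `confidences` (numeric vector,
#'   possibly empty). For paf: `n_points`. For tierpsy/omnipose: either
#'   `n_high_curvature_points` or `contour_curvature` + optional
#'   `curvature_threshold`, plus `width_max` / `width_min`.
#' @param conf_threshold confidence rule threshold (default 0.5).
#' @param min_points minimum complete-skeleton landmark count (default 14).
#' @param curvature_threshold contour curvature threshold used when raw
#'   curvatures are supplied (default 0.5, configurable — the reference value
#'   is unpublished).
#' @param width_ratio_max largest admissible max/min width ratio (default 2).
#' @return list with `status` ("ok"/"failed") and `reason`.
#' @export
classify_failure <- function(method, raw_output, conf_threshold = 0.5,
                             min_points = 14L, curvature_threshold = 0.5,
                             width_ratio_max = 2) {
  method <- match.arg(method, c("tierpsy", "dtc", "paf", "omnipose"))
  ok <- function() list(status = "ok", reason = NA_character_)
  fail <- function(r) list(status = "failed", reason = r)
  if (method == "dtc") {
    conf <- raw_output$confidences
    if (length(conf) == 0L || max(conf) <= conf_threshold)
      return(fail(sprintf("no skeleton above confidence %.2f", conf_threshold)))
    return(ok())
  }
  if (method == "paf") {
    if (is.null(raw_output$n_points)) stop("paf output needs n_points")
    if (raw_output$n_points < min_points)
      return(fail(sprintf("fewer than %d landmark points", min_points)))
    return(ok())
  }
  # tierpsy / omnipose contour heuristics
  n_peaks <- raw_output$n_high_curvature_points
  if (is.null(n_peaks)) {
    if (is.null(raw_output$contour_curvature))
      stop("tierpsy output needs n_high_curvature_points or contour_curvature")
    n_peaks <- sum(abs(raw_output$contour_curvature) > curvature_threshold)
  }
  if (n_peaks != 2L)
    return(fail(sprintf("%d supra-threshold curvature points (need exactly 2)", n_peaks)))
  if (!is.null(raw_output$width_max) && !is.null(raw_output$width_min)) {
    if (raw_output$width_min <= 0 ||
        raw_output$width_max / raw_output$width_min > width_ratio_max)
      return(fail("width ratio outside bound (likely coiled)"))
  }
  ok()
}

#' Tracking fidelity against ground-truth trajectories
#'
#' At every frame, ground-truth worms are matched to predicted tracks by
#' minimum-cost assignment on skeleton distance (pairs beyond `gate` are
#' forbidden). A ground-truth worm at frame t is a mismatch (`mme_t`) when it
#' is unmatched or its matched predicted track differs from the track matched
#' at the worm's first appearance. Fidelity = 1 - sum(mme_t) / sum(g_t).
#'
#' @param predicted list of `worm_trajectory`.
#' @param truth named list: worm id -> `skeleton_series`
#'   (or a list with `frames` and `skeletons`).
#' @param gate match gate in px (default: half the median skeleton arclength).
#' @return `track_match_result`: list with `frames`, `mme`, `g`, `fidelity`.
#' @export
tracking_fidelity <- function(predicted, truth, gate = NULL) {
  if (length(truth) == 0L) stop("empty ground truth")
  all_frames <- sort(unique(unlist(lapply(truth, `[[`, "frames"))))
  if (is.null(gate)) {
    lens <- unlist(lapply(truth, function(s)
      vapply(s$skeletons, skeleton_arclength, numeric(1L))))
    gate <- 0.5 * stats::median(lens)
  }
  pred_at <- function(tr, f) {
    i <- match(f, tr$frames)
    if (is.na(i)) NULL else tr$skeletons[[i]]
  }
  first_id <- list()    # ground-truth worm id -> predicted track id at entry
  mme <- integer(length(all_frames)); g <- integer(length(all_frames))
  for (fi in seq_along(all_frames)) {
    f <- all_frames[fi]
    gt_ids <- names(truth)[vapply(truth, function(s) f %in% s$frames, logical(1L))]
    g[fi] <- length(gt_ids)
    if (g[fi] == 0L) next
    pr_idx <- which(vapply(predicted, function(tr) f %in% tr$frames, logical(1L)))
    matched <- rep(NA_character_, length(gt_ids))
    if (length(pr_idx) > 0L) {
      cost <- matrix(BIG_COST, length(gt_ids), length(pr_idx))
      for (a in seq_along(gt_ids)) {
        ts <- truth[[gt_ids[a]]]
        sk <- ts$skeletons[[match(f, ts$frames)]]
        for (b in seq_along(pr_idx)) {
          d <- mean_point_distance(sk, pred_at(predicted[[pr_idx[b]]], f))
          if (d <= gate) cost[a, b] <- d
        }
      }
      m <- solve_assignment(cost)
      for (a in seq_along(gt_ids)) if (!is.na(m[a]))
        matched[a] <- predicted[[pr_idx[m[a]]]]$worm_id
    }
    for (a in seq_along(gt_ids)) {
      id <- gt_ids[a]
      if (is.na(matched[a])) { mme[fi] <- mme[fi] + 1L; next }
      if (is.null(first_id[[id]])) {
        first_id[[id]] <- matched[a]
      } else if (!identical(first_id[[id]], matched[a])) {
        mme[fi] <- mme[fi] + 1L
      }
    }
  }
  structure(list(frames = all_frames, mme = mme, g = g,
                 fidelity = 1 - sum(mme) / sum(g)),
            class = "track_match_result")
}

#' @export
print.track_match_result <- function(x, ...) {
  cat(sprintf("track_match_result: %d frames, sum(mme) = %d, sum(g) = %d, fidelity = %.4f\n",
              length(x$frames), sum(x$mme), sum(x$g), x$fidelity))
  invisible(x)
}
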