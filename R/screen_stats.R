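# Phenotypic-screen statistics: exemplar behavioural features from
# trajectories (median midbody speed, median absolute tail curvature),
# per-feature Pearson correlation between two trackers' feature tables with a
# histogram modal r, one-way F-statistics across drug/dose groups, and
# small-sample-corrected Hedge's d effect sizes averaged across doses.

#' Build a validated feature table
#'
#' @param df data.frame with a `well` column (unique ids), optional metadata
#'   columns `drug`, `dose`, `control`, and numeric feature columns.
#' @return data.frame of class `feature_table`.
#' @export
feature_table <- function(df) {
  if (!"well" %in% names(df)) stop("feature table needs a 'well' column")
  if (anyDuplicated(df$well)) stop("duplicate well ids")
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_columns <- function(df) {
  meta <- c("well", "drug", "dose", "control")
  names(df)[!names(df) %in% meta & vapply(df, is.numeric, logical(1L))]
}

#' Exemplar behavioural features per well
#'
#' Midbody speed: per-frame displacement of the centroid of the middle third
#' of the skeleton, converted to px/s; the well value is the median over
#' frames and worms. Tail curvature: mean absolute finite-difference
#' curvature (1/px) over the tail third; well value again the median.
#'
#' @param wells named list: well id -> list of `worm_trajectory` (or
#'   `skeleton_series`).
#' @param fps frames per second (default 25).
#' @return `feature_table` with columns `well`, `midbody_speed`,
#'   `tail_curvature`.
#' @export
basic_features <- function(wells, fps = 25) {
  if (length(wells) == 0L) stop("no trajectories supplied")
  rows <- lapply(names(wells), function(w) {
    speeds <- c(); curvs <- c()
    for (tr in wells[[w]]) {
      if (length(tr$frames) < 2L) next
      n <- nrow(tr$skeletons[[1L]])
      mid <- seq.int(floor(n / 3) + 1L, ceiling(2 * n / 3))
      tail_ <- seq.int(ceiling(2 * n / 3), n)
      cen <- t(vapply(tr$skeletons, function(s)
        colMeans(unclass(s)[mid, , drop = FALSE]), numeric(2L)))
      step <- diff(tr$frames)
      disp <- sqrt(rowSums(diff(cen)^2))
      speeds <- c(speeds, disp / step * fps)
      curvs <- c(curvs, vapply(tr$skeletons, function(s)
        mean(abs(skeleton_curvature(s)[tail_])), numeric(1L)))
    }
    if (length(speeds) == 0L) stop(sprintf("well %s has no usable trajectory", w))
    data.frame(well = w, midbody_speed = stats::median(speeds),
               tail_curvature = stats::median(curvs))
  })
  feature_table(do.call(rbind, rows))
}

#' Per-feature Pearson correlation between two feature tables
#'
#' Wells are matched by id; each shared numeric feature gets a Pearson r over
#' pairwise-complete wells (features with fewer than 3 complete pairs are
#' flagged and excluded). The modal r is read from a fixed-width histogram of
#' the r values (bin width 0.05 spanning [-1, 1]; the mode is the centre of
#' the fullest bin, first bin on ties).
#'
#' @param table_a,table_b `feature_table`s.
#' @param bin_width histogram bin width for the modal r (default 0.05).
#' @return list with `r` (named vector), `modal_r`, `excluded` (feature names).
#' @export
feature_correlations <- function(table_a, table_b, bin_width = 0.05) {
  common <- intersect(table_a$well, table_b$well)
  a <- table_a[match(common, table_a$well), , drop = FALSE]
  b <- table_b[match(common, table_b$well), , drop = FALSE]
  feats <- intersect(feature_columns(table_a), feature_columns(table_b))
  r <- stats::setNames(rep(NA_real_, length(feats)), feats)
  for (f in feats) {
    ok <- stats::complete.cases(a[[f]], b[[f]])
    if (sum(ok) >= 3L) r[f] <- stats::cor(a[[f]][ok], b[[f]][ok])
  }
  excluded <- names(r)[is.na(r)]
  rr <- r[!is.na(r)]
  modal_r <- NA_real_
  if (length(rr) > 0L) {
    breaks <- seq(-1, 1 + bin_width, by = bin_width)
    h <- graphics::hist(pmin(pmax(rr, -1), 1), breaks = breaks, plot = FALSE)
    modal_r <- h$mids[which.max(h$counts)]
  }
  list(r = rr, modal_r = modal_r, excluded = excluded)
}

#' One-way F-statistic per feature across groups
#'
#' Between-group over within-group mean square. Identical group means give
#' F = 0; zero within-group variance with distinct means is reported as +Inf.
#'
#' @param table `feature_table`.
#' @param groups group label per row of the table (e.g. drug x dose).
#' @return named numeric vector, one F per feature.
#' @export
feature_f_statistic <- function(table, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 wells")
  feats <- feature_columns(table)
  vapply(stats::setNames(feats, feats), function(f) {
    y <- table[[f]]
    ok <- is.finite(y)
    yy <- y[ok]; gg <- droplevels(groups[ok])
    gm <- tapply(yy, gg, mean)
    ni <- tapply(yy, gg, length)
    ssb <- sum(ni * (gm - mean(yy))^2)
    ssw <- sum((yy - gm[gg])^2)
    dfb <- nlevels(gg) - 1L; dfw <- length(yy) - nlevels(gg)
    if (ssb <= .Machine$double.eps * sum(yy^2)) return(0)
    if (ssw == 0) return(Inf)
    (ssb / dfb) / (ssw / dfw)
  }, numeric(1L))
}

#' Hedge's d standardized effect size
#'
#' Cohen's d with the small-sample correction
#' J = 1 - 3 / (4 (n_t + n_c) - 9):
#' d = (mean_t - mean_c) / s_pooled x J.
#'
#' @param treated,control numeric vectors, each with >= 2 values.
#' @return scalar d (NaN with a warning when the pooled variance is zero).
#' @export
hedges_d <- function(treated, control) {
  nt <- length(treated); nc <- length(control)
  if (nt < 2L || nc < 2L) stop("both samples need at least 2 values")
  sp2 <- ((nt - 1) * stats::var(treated) + (nc - 1) * stats::var(control)) /
    (nt + nc - 2)
  if (sp2 == 0) { warning("zero pooled variance; d undefined"); return(NaN) }
  J <- 1 - 3 / (4 * (nt + nc) - 9)
  (mean(treated) - mean(control)) / sqrt(sp2) * J
}

#' Mean absolute Hedge's d across doses of a drug
#'
#' For each feature: Hedge's d of each dose of `drug` against the pooled
#' control wells, absolute values averaged over doses.
#'
#' @param table `feature_table` with `drug`, `dose`, `control` columns.
#' @param drug drug name.
#' @return named numeric vector (one mean |d| per feature).
#' @export
mean_abs_effect <- function(table, drug) {
  need <- c("drug", "dose", "control")
  if (!all(need %in% names(table))) stop("table needs drug, dose, control columns")
  ctrl <- table[table$control %in% TRUE, , drop = FALSE]
  if (nrow(ctrl) < 2L) stop("need at least 2 control wells")
  trt <- table[table$drug == drug & !(table$control %in% TRUE), , drop = FALSE]
  doses <- sort(unique(trt$dose))
  if (length(doses) == 0L) stop(sprintf("no treated wells for drug '%s'", drug))
  feats <- feature_columns(table)
  vapply(stats::setNames(feats, feats), function(f) {
    ds <- vapply(doses, function(d) {
      x <- trt[[f]][trt$dose == d]
      if (length(x) < 2L) return(NA_real_)
      abs(hedges_d(x, ctrl[[f]]))
    }, numeric(1L))
    mean(ds, na.rm = TRUE)
  }, numeric(1L))
}
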