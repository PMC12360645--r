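# Shared fixtures (memoised per test run) and independent brute-force
# oracles. Oracles are deliberately written as plain loops, independent of
# the package's vectorised implementations.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_recording <- function() fixture("tiny_recording", function() {
  simulate_recording(2, 4, dim = c(160L, 160L), worm_length = 40,
                     n_points = 25L, worm_width = 3, seed = 7)
})

single_worm_recording <- function() fixture("single_worm", function() {
  simulate_recording(1, 8, dim = c(160L, 160L), worm_length = 40,
                     n_points = 25L, worm_width = 3, seed = 9)
})

tiny_shape_space <- function(D = 12L) fixture(paste0("space", D), function() {
  rec <- tiny_recording()
  sks <- unlist(rec$skeletons, recursive = FALSE)
  fit_shape_space(lapply(sks, resample_equal_arclength, n = 25L), D = D)
})

# straight horizontal skeleton of given length, centred at (cx, cy)
straight_skeleton <- function(cx, cy, len = 20, n = 5L) {
  as_skeleton(cbind(x = seq(cx - len / 2, cx + len / 2, length.out = n),
                    y = rep(cy, n)))
}

# smooth random open curve with n points: random walk on heading
random_skeleton <- function(n = 9L, step = 4) {
  th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2L, 0, 0.5)))
  p <- rbind(c(0, 0), apply(cbind(cos(th), sin(th)) * step, 2L, cumsum))
  as_skeleton(p + matrix(runif(2, 0, 50), n, 2L, byrow = TRUE))
}

# Two collinear worms where the faster one overtakes the slower: spatial
# assignment costs tie by construction, latents are distinct, and greedy
# centroid matching provably swaps identities.
crossing_fixture <- function() {
  xa <- c(0, 12, 24, 36, 48)
  xb <- c(20, 26, 32, 38, 44)
  dets <- list(); truth_a <- list(); truth_b <- list()
  for (f in 1:5) {
    sa <- straight_skeleton(xa[f], 0); sb <- straight_skeleton(xb[f], 0)
    dets[[length(dets) + 1L]] <- list(frame = f, skeleton = sa,
                                      confidence = 1, latent = c(0, 0))
    dets[[length(dets) + 1L]] <- list(frame = f, skeleton = sb,
                                      confidence = 1, latent = c(5, 5))
    truth_a[[f]] <- sa; truth_b[[f]] <- sb
  }
  list(detections = dets,
       truth = list(A = skeleton_series(1:5, truth_a, "A"),
                    B = skeleton_series(1:5, truth_b, "B")))
}

# --- independent oracles ---------------------------------------------------

oracle_rmsd <- function(p, t_) {
  best <- Inf
  for (orient in 1:2) {
    q <- if (orient == 1L) p else p[rev(seq_len(nrow(p))), , drop = FALSE]
    ss <- 0
    for (i in seq_len(nrow(q)))
      ss <- ss + (q[i, 1L] - t_[i, 1L])^2 + (q[i, 2L] - t_[i, 2L])^2
    best <- min(best, sqrt(ss / nrow(q)))
  }
  best
}

oracle_segment_distance <- function(p, t_) {
  total <- 0
  for (i in seq_len(nrow(p))) {
    dmin <- Inf
    for (j in seq_len(nrow(t_) - 1L)) {
      a <- t_[j, ]; b <- t_[j + 1L, ]; v <- b - a
      L2 <- sum(v * v)
      tt <- if (L2 == 0) 0 else sum((p[i, ] - a) * v) / L2
      tt <- min(max(tt, 0), 1)
      proj <- a + tt * v
      dmin <- min(dmin, sqrt(sum((p[i, ] - proj)^2)))
    }
    total <- total + dmin
  }
  total / nrow(p)
}

oracle_f_statistic <- function(y, g) {
  fit <- stats::anova(stats::lm(y ~ factor(g)))
  fit$`F value`[1L]
}

# brute-force assignment by permutation enumeration (nrow <= ncol, small)
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 7L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf; best_sel <- NULL
  for (pm in perms(seq_len(m))) {
    sel <- pm[seq_len(n)]
    val <- sum(cost[cbind(seq_len(n), sel)])
    if (val < best) { best <- val; best_sel <- sel }
  }
  list(cost = best, match = best_sel)
}

# brute-force tracking fidelity under the persistent-identity definition;
# per-frame matching by permutation enumeration on mean point distance
oracle_fidelity <- function(predicted, truth, gate) {
  frames <- sort(unique(unlist(lapply(truth, function(s) s$frames))))
  first_id <- list(); mme_sum <- 0L; g_sum <- 0L
  dist_sk <- function(a, b) {
    a <- unclass(a); b <- unclass(b)
    d1 <- mean(sqrt(rowSums((a - b)^2)))
    d2 <- mean(sqrt(rowSums((a[rev(seq_len(nrow(a))), ] - b)^2)))
    min(d1, d2)
  }
  for (f in frames) {
    gt <- names(truth)[vapply(truth, function(s) f %in% s$frames, logical(1L))]
    g_sum <- g_sum + length(gt)
    pr <- Filter(function(tr) f %in% tr$frames, predicted)
    cm <- matrix(1e9, length(gt), max(length(pr), 1L))
    for (a in seq_along(gt)) {
      sk <- truth[[gt[a]]]$skeletons[[match(f, truth[[gt[a]]]$frames)]]
      for (b in seq_along(pr)) {
        d <- dist_sk(sk, pr[[b]]$skeletons[[match(f, pr[[b]]$frames)]])
        if (d <= gate) cm[a, b] <- d
      }
    }
    match_ids <- rep(NA_character_, length(gt))
    if (length(pr) > 0L && length(gt) > 0L) {
      if (length(gt) <= ncol(cm)) {
        sol <- oracle_assignment(cm)
        for (a in seq_along(gt))
          if (cm[a, sol$match[a]] < 1e9)
            match_ids[a] <- pr[[sol$match[a]]]$worm_id
      } else {
        sol <- oracle_assignment(t(cm))
        for (b in seq_along(pr))
          if (cm[sol$match[b], b] < 1e9)
            match_ids[sol$match[b]] <- pr[[b]]$worm_id
      }
    }
    for (a in seq_along(gt)) {
      id <- gt[a]
      if (is.na(match_ids[a])) { mme_sum <- mme_sum + 1L; next }
      if (is.null(first_id[[id]])) first_id[[id]] <- match_ids[a]
      else if (!identical(first_id[[id]], match_ids[a])) mme_sum <- mme_sum + 1L
    }
  }
  1 - mme_sum / g_sum
}

detections_from_recording <- function(rec, frames = NULL, latents = NULL) {
  if (is.null(frames)) frames <- seq_along(rec$skeletons)
  dets <- list()
  for (f in frames) for (id in names(rec$skeletons[[f]])) {
    dets[[length(dets) + 1L]] <- list(
      frame = f, skeleton = rec$skeletons[[f]][[id]], confidence = 1,
      latent = if (is.null(latents)) NULL else latents[[id]])
  }
  dets
}

truth_series_from_recording <- function(rec, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(rec$skeletons)
  ids <- names(rec$skeletons[[frames[1L]]])
  out <- lapply(ids, function(id)
    skeleton_series(frames, lapply(frames, function(f) rec$skeletons[[f]][[id]]), id))
  names(out) <- ids
  out
}
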