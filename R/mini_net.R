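# A deliberately small reference predictor that exercises the grid training
# and decoding contract at desk scale. It is NOT a re-creation of the
# full-scale detector: the 11-frame stack is pooled into three channels
# (temporal mean, central frame, darkest projection), a patch centred on each
# grid cell is passed through one strided patch-linear layer (equivalent to a
# single convolution with stride = cell size) with ReLU, and linear heads emit
# a confidence logit, scaled shape-space coefficients for the 3 central
# frames, and an L-dimensional latent vector. Training is full-batch Adam on
# confidence binary cross-entropy + masked coefficient MSE + a latent
# consistency term pulling latents of the same worm in overlapping cells
# together. The confidence bias is initialised toward an empty-scene prior so
# an untrained model detects nothing.

pool2 <- function(m, pool) {
  if (pool <= 1L) return(m)
  n <- nrow(m) %/% pool
  mm <- matrix(0, n, n)
  for (a in seq_len(pool)) for (b in seq_len(pool))
    mm <- mm + m[seq(a, by = pool, length.out = n),
                 seq(b, by = pool, length.out = n)]
  mm / pool^2
}

clip_cell_features <- function(clip, geom, patch = 32L, pool = 1L) {
  fr <- clip$frames
  d <- dim(fr)
  chans <- list(apply(fr, c(1L, 2L), mean),
                fr[, , (d[3L] + 1L) %/% 2L],
                apply(fr, c(1L, 2L), min))
  half <- patch %/% 2L
  q <- patch %/% pool
  n_cells <- geom$g_rows * geom$g_cols
  X <- matrix(0, n_cells, 3L * q * q)
  i <- 0L
  for (c in seq_len(geom$g_cols)) for (r in seq_len(geom$g_rows)) {
    i <- i + 1L
    # patch rows/cols in 1-based matrix indices, clipped at the borders
    r0 <- round(geom$centre_y[r, c]) + 1L - half
    c0 <- round(geom$centre_x[r, c]) + 1L - half
    rs <- r0:(r0 + patch - 1L); cs <- c0:(c0 + patch - 1L)
    rok <- rs >= 1L & rs <= d[1L]; cok <- cs >= 1L & cs <= d[2L]
    for (ch in 1:3) {
      block <- matrix(0, patch, patch)
      block[rok, cok] <- chans[[ch]][rs[rok], cs[cok]]
      X[i, ((ch - 1L) * q * q + 1L):(ch * q * q)] <- pool2(block, pool)
    }
  }
  X
}

flip_clip <- function(cl, horizontal = TRUE) {
  d <- dim(cl$frames)
  if (horizontal) {
    cl$frames <- cl$frames[, d[2L]:1L, , drop = FALSE]
  } else {
    cl$frames <- cl$frames[d[1L]:1L, , , drop = FALSE]
  }
  cl$annotations <- lapply(cl$annotations, function(a) lapply(a, function(s) {
    s <- unclass(s)
    if (horizontal) s[, 1L] <- d[2L] - 1 - s[, 1L] else s[, 2L] <- d[1L] - 1 - s[, 2L]
    as_skeleton(s)
  }))
  cl
}

# cell order used by clip_cell_features / predict_clip: column-major (r fast)
cell_index_map <- function(geom) {
  cbind(row = rep(seq_len(geom$g_rows), geom$g_cols),
        col = rep(seq_len(geom$g_cols), each = geom$g_rows))
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

adam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  st$t <- st$t + 1L
  mh <- st$m / (1 - b1^st$t); vh <- st$v / (1 - b2^st$t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the tiny reference grid predictor on simulated clips
#'
#' @param clips list of background-subtracted `worm_clip`s sharing geometry,
#'   with ground-truth annotations.
#' @param space `shape_space` for coefficient targets (its N must match the
#'   clips' annotation skeletons).
#' @param epochs training epochs (default 150).
#' @param seed RNG seed; training is reproducible given the seed.
#' @param cell_size grid cell side (default 16).
#' @param cutoff target-assignment radius in px; default 0.6 x the median
#'   annotated worm length, the same worm-relative radius as the full-scale
#'   48 px cutoff at 80 px worms.
#' @param hidden hidden width (default 64).
#' @param patch receptive-field side in px (default 32).
#' @param pool mean-pooling factor applied to the patch (default 1 = none).
#' @param L latent dimension (default 8).
#' @param lr Adam learning rate (default 1e-3, the full-scale setting).
#' @param w_coef,w_lat loss weights for the coefficient and latent terms.
#' @param augment add the three mirror images of every clip to the training
#'   set (default TRUE; the scene statistics are mirror symmetric).
#' @param verbose print the loss every 25 epochs.
#' @return `mini_predictor` model object; `$loss_history` has one entry per
#'   epoch.
#' @export
mini_train <- function(clips, space, epochs = 150L, seed = 1L, cell_size = 16L,
                       cutoff = NULL, hidden = 64L, patch = 32L, pool = 1L,
                       L = 8L, lr = 1e-3, w_coef = 1, w_lat = 0.1,
                       augment = TRUE, verbose = FALSE) {
  if (length(clips) < 1L) stop("no clips")
  d <- dim(clips[[1L]]$frames)
  for (cl in clips) if (!identical(dim(cl$frames), d))
    stop("clips must share frame geometry")
  pad <- pad_to_multiple(array(0, d), m = cell_size)
  geom <- grid_geometry(dim(pad$image)[1:2], cell_size)
  if (is.null(cutoff)) {
    lens <- vapply(clips, function(cl)
      skeleton_arclength(cl$annotations[[2L]][[1L]]), numeric(1L))
    cutoff <- 0.6 * stats::median(lens)
  }
  if (augment)
    clips <- c(clips,
               lapply(clips, flip_clip, horizontal = TRUE),
               lapply(clips, flip_clip, horizontal = FALSE),
               lapply(clips, function(cl) flip_clip(flip_clip(cl), FALSE)))
  D <- space$D
  coef_scale <- cell_size / 2   # coefficients are in px relative to the cell

  # assemble the training matrices
  n_cells <- geom$g_rows * geom$g_cols
  idxmap <- cell_index_map(geom)
  Xs <- vector("list", length(clips)); Cs <- Ys <- Gs <- vector("list", length(clips))
  for (ci in seq_along(clips)) {
    cl <- clips[[ci]]
    cl$frames <- pad_to_multiple(cl$frames, cell_size)$image
    Xs[[ci]] <- clip_cell_features(cl, geom, patch, pool)
    tg <- assign_targets(cl$annotations, space, dim(cl$frames)[1:2],
                         cell_size, cutoff, K = 1L, L = L)
    # disentangled targets: per-frame centroid offset from the cell centre
    # (a localisation task) + shape coefficients relative to the centroid
    # (translation invariant); recombined exactly at prediction time
    conf <- numeric(n_cells); yc <- matrix(0, n_cells, 6L + 3L * D)
    grp <- rep(NA_character_, n_cells)
    for (i in seq_len(n_cells)) {
      r <- idxmap[i, 1L]; c <- idxmap[i, 2L]
      conf[i] <- tg$confidence[r, c, 1L]
      if (conf[i] > 0) {
        id <- tg$worm_ids[r, c, 1L]
        ctr_cell <- c(geom$centre_x[r, c], geom$centre_y[r, c])
        off <- numeric(6L); sh <- matrix(0, 3L, D)
        for (f in 1:3) {
          sk <- cl$annotations[[f]][[id]]
          cen <- skeleton_centroid(sk)
          off[(2L * f - 1L):(2L * f)] <- cen - ctr_cell
          sh[f, ] <- encode_skeleton(sk, space, cen)
        }
        yc[i, ] <- c(off, as.vector(sh)) / coef_scale
        grp[i] <- paste0(ci, ":", id)
      }
    }
    Cs[[ci]] <- conf; Ys[[ci]] <- yc; Gs[[ci]] <- grp
  }
  X <- do.call(rbind, Xs); conf_t <- unlist(Cs)
  Y <- do.call(rbind, Ys); grp <- unlist(Gs)
  xm <- colMeans(X); xs <- pmax(apply(X, 2L, stats::sd), 1e-6)
  X <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  n <- nrow(X); p <- ncol(X)
  mask <- conf_t > 0
  grp_f <- factor(grp[mask])

  set.seed(seed)
  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  wc <- matrix(stats::rnorm(hidden, 0, 0.01), hidden, 1L); bc <- -2
  n_out <- 6L + 3L * D
  Ws <- matrix(stats::rnorm(hidden * n_out, 0, 0.01), hidden, n_out)
  bs <- numeric(n_out)
  Wl <- matrix(stats::rnorm(hidden * L, 0, 0.01), hidden, L)

  st <- lapply(list(W1, b1, wc, bc, Ws, bs, Wl),
               function(p_) list(m = p_ * 0, v = p_ * 0, t = 0L))
  names(st) <- c("W1", "b1", "wc", "bc", "Ws", "bs", "Wl")
  loss_hist <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    A1 <- sweep(X %*% W1, 2L, b1, "+"); H1 <- relu(A1)
    logit <- drop(H1 %*% wc) + bc
    pc <- sigmoid(logit)
    Yp <- sweep(H1 %*% Ws, 2L, bs, "+")
    Lt <- H1 %*% Wl

    bce <- -mean(conf_t * log(pmax(pc, 1e-12)) +
                 (1 - conf_t) * log(pmax(1 - pc, 1e-12)))
    res <- (Yp - Y); res[!mask, ] <- 0
    mse <- sum(res^2) / (max(sum(mask), 1L) * n_out)
    # latent consistency: variance of latents within each worm's cells
    Lm <- Lt[mask, , drop = FALSE]
    mu_g <- rowsum(Lm, grp_f) / as.vector(table(grp_f))
    dev <- Lm - mu_g[as.integer(grp_f), , drop = FALSE]
    lat <- sum(dev^2) / (max(sum(mask), 1L) * ncol(Lm))
    loss_hist[ep] <- bce + w_coef * mse + w_lat * lat
    if (verbose && ep %% 25L == 0L)
      message(sprintf("epoch %3d  loss %.5f (bce %.4f mse %.4f lat %.4f)",
                      ep, loss_hist[ep], bce, mse, lat))

    # gradients
    g_logit <- (pc - conf_t) / n
    g_Yp <- res * (2 * w_coef / (max(sum(mask), 1L) * n_out))
    g_Lt <- matrix(0, n, L)
    g_Lt[mask, ] <- dev * (2 * w_lat / (max(sum(mask), 1L) * ncol(Lm)))
    g_H1 <- tcrossprod(g_logit, drop(wc)) + g_Yp %*% t(Ws) + g_Lt %*% t(Wl)
    g_A1 <- g_H1 * (A1 > 0)
    g <- list(W1 = crossprod(X, g_A1), b1 = colSums(g_A1),
              wc = crossprod(H1, matrix(g_logit)), bc = sum(g_logit),
              Ws = crossprod(H1, g_Yp), bs = colSums(g_Yp),
              Wl = crossprod(H1, g_Lt))
    pars <- list(W1 = W1, b1 = b1, wc = wc, bc = bc, Ws = Ws, bs = bs, Wl = Wl)
    for (nm in names(pars)) {
      upd <- adam_step(pars[[nm]], g[[nm]], st[[nm]], lr)
      pars[[nm]] <- upd$p; st[[nm]] <- upd$st
    }
    W1 <- pars$W1; b1 <- pars$b1; wc <- pars$wc; bc <- pars$bc
    Ws <- pars$Ws; bs <- pars$bs; Wl <- pars$Wl
  }

  structure(list(W1 = W1, b1 = b1, wc = wc, bc = bc, Ws = Ws, bs = bs, Wl = Wl,
                 feat_mean = xm, feat_sd = xs, patch = as.integer(patch),
                 pool = as.integer(pool),
                 cell_size = as.integer(cell_size), D = D, L = as.integer(L),
                 coef_scale = coef_scale, cutoff = cutoff,
                 loss_history = loss_hist, seed = seed),
            class = "mini_predictor")
}

#' @export
print.mini_predictor <- function(x, ...) {
  cat(sprintf("mini_predictor: patch %d px, cell %d px, D = %d, L = %d; final loss %.4f\n",
              x$patch, x$cell_size, x$D, x$L,
              if (length(x$loss_history)) x$loss_history[length(x$loss_history)] else NA))
  invisible(x)
}

#' Run the tiny reference predictor on one clip
#'
#' Pads the clip to a multiple of the cell size, extracts per-cell patch
#' features, and fills a K = 1 `prediction_grid` with the model's confidence,
#' coefficient and latent outputs; decode with [decode_grid()].
#'
#' @param model a `mini_predictor`.
#' @param clip background-subtracted `worm_clip`.
#' @param space the `shape_space` the model was trained with.
#' @return a `prediction_grid`.
#' @export
predict_clip <- function(model, clip, space) {
  if (model$D != space$D) stop("model D does not match shape space")
  fr <- pad_to_multiple(clip$frames, model$cell_size)$image
  geom <- grid_geometry(dim(fr)[1:2], model$cell_size)
  cl <- clip; cl$frames <- fr
  X <- clip_cell_features(cl, geom, model$patch, model$pool %||% 1L)
  if (ncol(X) != length(model$feat_mean)) stop("incompatible clip shape")
  X <- sweep(sweep(X, 2L, model$feat_mean), 2L, model$feat_sd, "/")
  H1 <- relu(sweep(X %*% model$W1, 2L, model$b1, "+"))
  pc <- sigmoid(drop(H1 %*% model$wc) + model$bc)
  Yp <- sweep(H1 %*% model$Ws, 2L, model$bs, "+") * model$coef_scale
  Lt <- H1 %*% model$Wl
  D <- model$D
  grid <- new_prediction_grid(geom, K = 1L, D = D, L = model$L)
  idxmap <- cell_index_map(geom)
  for (i in seq_len(nrow(idxmap))) {
    r <- idxmap[i, 1L]; c <- idxmap[i, 2L]
    grid$confidence[r, c, 1L] <- pc[i]
    ctr_cell <- c(geom$centre_x[r, c], geom$centre_y[r, c])
    off <- Yp[i, 1:6]
    sh <- matrix(Yp[i, -(1:6)], 3L, D)
    for (f in 1:3) {
      sk <- decode_skeleton(sh[f, ], space,
                            ctr_cell + off[(2L * f - 1L):(2L * f)])
      grid$coeffs[r, c, 1L, f, ] <- encode_skeleton(sk, space, ctr_cell)
    }
    grid$latent[r, c, 1L, ] <- Lt[i, ]
  }
  grid
}

#' Detection recall of a predictor on held-out clips
#'
#' A ground-truth worm (central frame) counts as recalled when, after decoding
#' at the confidence threshold and non-maximum suppression, some detection's
#' orientation-minimised mean point distance to it is below
#' `match_frac` x worm length.
#'
#' @param model `mini_predictor`.
#' @param clips held-out `worm_clip`s.
#' @param space shape space.
#' @param conf_threshold decoding threshold (default 0.5).
#' @param match_frac match radius as a fraction of worm length (default 0.25).
#' @return list with `recall`, `n_truth`, `n_matched`.
#' @export
detection_recall <- function(model, clips, space, conf_threshold = 0.5,
                             match_frac = 0.25) {
  n_truth <- 0L; n_match <- 0L
  for (cl in clips) {
    grid <- predict_clip(model, cl, space)
    dets <- decode_grid(grid, space, conf_threshold, frames = 1:3)
    dets <- dets[vapply(dets, `[[`, numeric(1L), "frame") == 2]
    dets <- deduplicate(dets, min_separation = 0.25 *
                          skeleton_arclength(cl$annotations[[2L]][[1L]]))
    for (id in names(cl$annotations[[2L]])) {
      truth <- cl$annotations[[2L]][[id]]
      tol <- match_frac * skeleton_arclength(truth)
      n_truth <- n_truth + 1L
      if (length(dets) > 0L &&
          min(vapply(dets, function(d) mean_point_distance(d$skeleton, truth),
                     numeric(1L))) < tol)
        n_match <- n_match + 1L
    }
  }
  list(recall = if (n_truth) n_match / n_truth else NA_real_,
       n_truth = n_truth, n_matched = n_match)
}
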