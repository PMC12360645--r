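# Synthetic crawling-worm video generator. Worms are serpenoid undulators:
# the midline is an inextensible unit-speed curve of fixed length whose
# curvature is a travelling sine wave kappa(s, t) = a * sin(2*pi*s/lambda -
# phase(t)), laid down behind a head point that advances along a slowly
# drifting heading. This is not a biomechanical model; it is a smooth
# ground-truth generator with the features the downstream stages care about:
# constant arclength, undulatory motion, optional dwelling and coiling,
# worm-worm overlap, and a static non-uniform background with egg-like
# distractors that a rank-1 temporal model can remove exactly.

#' Build a static non-uniform background image
#'
#' Mid-grey field with a smooth lawn-edge radial gradient and a number of
#' small dark Gaussian blobs emulating eggs. Intensities are on a 0..1 scale.
#'
#' @param dim c(H, W) frame size in pixels.
#' @param n_eggs number of egg-like distractor blobs.
#' @param base base intensity.
#' @param lawn_amplitude amplitude of the radial lawn-edge gradient.
#' @param seed RNG seed for egg placement.
#' @return H x W matrix.
#' @export
make_background <- function(dim = c(512L, 512L), n_eggs = 20L, base = 0.55,
                            lawn_amplitude = 0.08, seed = 1L) {
  H <- dim[1L]; W <- dim[2L]
  set.seed(seed)
  yy <- matrix(seq_len(H) - 1, H, W)
  xx <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  r <- sqrt((yy - (H - 1) / 2)^2 + (xx - (W - 1) / 2)^2)
  bg <- base + lawn_amplitude * cos(pi * r / max(H, W))
  if (n_eggs > 0L) {
    ex <- stats::runif(n_eggs, 2, W - 3)
    ey <- stats::runif(n_eggs, 2, H - 3)
    es <- stats::runif(n_eggs, 1.0, 2.0)
    ea <- stats::runif(n_eggs, 0.10, 0.20)
    for (i in seq_len(n_eggs)) {
      x0 <- max(1L, floor(ex[i] - 5)); x1 <- min(W, ceiling(ex[i] + 5))
      y0 <- max(1L, floor(ey[i] - 5)); y1 <- min(H, ceiling(ey[i] + 5))
      sub_y <- y0:y1; sub_x <- x0:x1
      d2 <- outer((sub_y - 1 - ey[i])^2, (sub_x - 1 - ex[i])^2, "+")
      bg[sub_y, sub_x] <- bg[sub_y, sub_x] - ea[i] * exp(-d2 / (2 * es[i]^2))
    }
  }
  bg
}

# Tapered half-width profile: widths strictly positive, ~0 at head and tail.
worm_width_profile <- function(n, max_half_width) {
  u <- seq(0, 1, length.out = n)
  pmax(max_half_width * sqrt(pmax(4 * u * (1 - u), 0)), 0.05)
}

# Lay the midline down behind the head: unit-speed curve of total length L
# with serpenoid curvature, head first. Returns an n x 2 matrix.
serpenoid_midline <- function(head, heading, phase, length_px, n_points,
                              amplitude, wavelength) {
  ds <- length_px / (n_points - 1L)
  s <- seq(0, length_px, length.out = n_points)
  kappa <- amplitude * sin(2 * pi * s / wavelength - phase)
  # heading of the tangent pointing head->tail, integrated from the head
  theta <- heading + pi + cumsum(c(0, (kappa[-1L] + kappa[-n_points]) / 2 * ds))
  x <- head[1L] + cumsum(c(0, cos(theta[-1L]) * ds))
  y <- head[2L] + cumsum(c(0, sin(theta[-1L]) * ds))
  cbind(x = x, y = y)
}

# Stamp one worm into a frame: darkest-value combination of the current frame
# and (background - contrast) over the tube midline +/- half-width.
stamp_worm <- function(frame, background, midline, half_widths, contrast,
                       offsets) {
  H <- nrow(frame); W <- ncol(frame)
  # dense resampling at ~0.5 px steps so stamped disks cover the tube
  total <- skeleton_arclength(midline)
  n_dense <- max(2L, ceiling(total / 0.5) + 1L)
  dense <- unclass(resample_equal_arclength(midline, n_dense))
  hw <- stats::approx(seq(0, 1, length.out = length(half_widths)), half_widths,
                      xout = seq(0, 1, length.out = n_dense))$y
  npt <- nrow(dense); noff <- nrow(offsets)
  ip <- rep.int(seq_len(npt), rep.int(noff, npt))
  cx <- round(dense[ip, 1L]) + offsets[, 1L]
  cy <- round(dense[ip, 2L]) + offsets[, 2L]
  keep <- (cx - dense[ip, 1L])^2 + (cy - dense[ip, 2L])^2 <= hw[ip]^2 &
    cx >= 0 & cx < W & cy >= 0 & cy < H
  if (!any(keep)) return(frame)
  idx <- unique((cy[keep] + 1L) + cx[keep] * H)
  frame[idx] <- pmin(frame[idx], background[idx] - contrast)
  frame
}

disk_offsets <- function(max_radius) {
  r <- ceiling(max_radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= (max_radius + 1)^2, , drop = FALSE])
}

#' Simulate a multi-worm crawling recording
#'
#' Generates a grayscale video (0..1 intensities, worms dark on a static
#' non-uniform background) together with the ground-truth midline of every
#' worm in every frame. Worms undulate smoothly, optionally dwell (pause), and
#' optionally coil into self-intersecting postures; the midline arclength is
#' constant by construction. Deterministic given `seed`.
#'
#' @param n_worms number of worms (>= 0).
#' @param duration_s recording duration in seconds.
#' @param fps frames per second (default 25).
#' @param dim c(H, W) frame size (default 512 x 512).
#' @param worm_length worm length in px (default 80, ~1 mm at 12.4 um/px).
#' @param n_points skeleton points per worm (default 49).
#' @param worm_width full worm width in px (default 4).
#' @param contrast worm darkness below background (default 0.3).
#' @param noise_sd per-pixel Gaussian noise sd (default 0 = noise-free).
#' @param background optional H x W background matrix; built with
#'   [make_background()] when NULL.
#' @param dwell_prob per-frame probability of entering a dwelling episode.
#' @param coil_prob per-frame probability of starting a coiling episode.
#' @param speed_range c(min, max) worm speed in px/s; the default 12-18 px/s
#'   is ~0.15-0.22 mm/s at 12.4 um/px, a typical on-food crawl.
#' @param heading_noise sd of the per-sqrt(second) heading drift (rad).
#' @param seed RNG seed (required).
#' @return `worm_recording`: list with `frames` (H x W x T array),
#'   `skeletons` (length-T list; each a named list worm id -> N x 2 skeleton,
#'   head first), `background`, `fps`, `pixel_size_um`, and the geometry
#'   parameters.
#' @export
simulate_recording <- function(n_worms, duration_s, fps = 25, dim = c(512L, 512L),
                               worm_length = 80, n_points = 49L, worm_width = 4,
                               contrast = 0.3, noise_sd = 0, background = NULL,
                               dwell_prob = 0.004, coil_prob = 0,
                               speed_range = c(12, 18), heading_noise = 0.25,
                               seed) {
  if (missing(seed)) stop("seed must be given for reproducibility")
  if (n_worms < 0L) stop("n_worms must be >= 0")
  if (duration_s <= 0) stop("duration_s must be positive")
  H <- dim[1L]; W <- dim[2L]
  if (is.null(background)) background <- make_background(dim, seed = seed)
  stopifnot(nrow(background) == H, ncol(background) == W)
  set.seed(seed)
  T_ <- as.integer(round(duration_s * fps))
  margin <- worm_length * 0.6
  if (n_worms > 0L && (2 * margin >= W || 2 * margin >= H))
    stop("frame too small to place worms of this length (sizing error)")

  dt <- 1 / fps
  wavelength <- 0.9 * worm_length
  base_amp <- 2 * pi * 0.85 / wavelength     # ~0.85 rad max bend angle
  coil_amp <- 2 * pi * 2.6 / wavelength      # self-intersecting when coiling
  hw <- worm_width_profile(n_points, worm_width / 2)
  offsets <- disk_offsets(worm_width / 2)

  worms <- lapply(seq_len(n_worms), function(i) {
    list(head = c(stats::runif(1, margin, W - 1 - margin),
                  stats::runif(1, margin, H - 1 - margin)),
         heading = stats::runif(1, 0, 2 * pi),
         phase = stats::runif(1, 0, 2 * pi),
         speed = stats::runif(1, speed_range[1L], speed_range[2L]),
         freq = stats::runif(1, 0.4, 0.6),    # undulation Hz
         turn = 0,                            # smoothed turn rate, rad/s
         amp = base_amp, dwelling = FALSE, coiling = 0L)
  })

  frames <- array(0, c(H, W, T_))
  skeletons <- vector("list", T_)
  for (t in seq_len(T_)) {
    frame <- background
    ann <- list()
    for (i in seq_along(worms)) {
      w <- worms[[i]]
      mid <- serpenoid_midline(w$head, w$heading, w$phase, worm_length,
                               n_points, w$amp, wavelength)
      frame <- stamp_worm(frame, background, mid, hw, contrast, offsets)
      ann[[sprintf("w%02d", i)]] <- as_skeleton(mid)

      # advance state
      if (w$coiling > 0L) {
        w$coiling <- w$coiling - 1L
        w$amp <- coil_amp
      } else {
        w$amp <- base_amp
        if (coil_prob > 0 && stats::runif(1) < coil_prob)
          w$coiling <- as.integer(round(fps))  # one-second coil
      }
      if (w$dwelling) {
        if (stats::runif(1) < 0.05) w$dwelling <- FALSE
      } else if (stats::runif(1) < dwell_prob) w$dwelling <- TRUE
      v <- if (w$dwelling || w$coiling > 0L) 0 else w$speed
      w$phase <- w$phase + 2 * pi * w$freq * dt
      step_heading <- w$heading + 0.35 * sin(w$phase)  # head sway
      w$head <- w$head + v * dt * c(cos(step_heading), sin(step_heading))
      # smooth (Ornstein-Uhlenbeck) turn rate so the body never jumps
      w$turn <- w$turn * exp(-dt / 1.5) +
        stats::rnorm(1, 0, heading_noise) * sqrt(dt)
      steer <- w$turn * dt
      # soft wall: rate-limited steering back toward the arena centre
      if (w$head[1L] < margin || w$head[1L] > W - 1 - margin ||
          w$head[2L] < margin || w$head[2L] > H - 1 - margin) {
        ctr <- c((W - 1) / 2, (H - 1) / 2)
        want <- atan2(ctr[2L] - w$head[2L], ctr[1L] - w$head[1L])
        d_ang <- atan2(sin(want - w$heading), cos(want - w$heading))
        steer <- steer + sign(d_ang) * min(abs(d_ang), 1.2 * dt)
      }
      w$heading <- w$heading + steer
      worms[[i]] <- w
    }
    if (noise_sd > 0) frame <- frame + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    frames[, , t] <- frame
    skeletons[[t]] <- ann
  }
  structure(list(frames = frames, skeletons = skeletons,
                 background = background, fps = fps, pixel_size_um = 12.4,
                 n_worms = n_worms, worm_length = worm_length,
                 n_points = n_points, worm_width = worm_width,
                 contrast = contrast, seed = seed),
            class = "worm_recording")
}

#' @export
print.worm_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("worm_recording: %d frames of %d x %d px, %d worm(s), %g fps\n",
              d[3L], d[1L], d[2L], x$n_worms, x$fps))
  invisible(x)
}

#' Sample an 11-frame clip spanning a 2, 4 or 8 second window
#'
#' Takes `T` frames at uniform temporal stride covering `duration_s` seconds
#' of the recording; ground-truth skeletons are attached only to the three
#' central sampled frames, matching the training-clip convention.
#'
#' @param recording a `worm_recording`.
#' @param duration_s window length in seconds; 2, 4 and 8 are the standard
#'   choices (stride 5, 10, 20 at 25 fps).
#' @param T number of sampled frames (odd, default 11).
#' @param start first frame of the window (1-based, default 1).
#' @return `worm_clip`: list with `frames` (H x W x T), `annotations` (list of
#'   3 named skeleton lists for the central frames), `central` (local indices
#'   of annotated frames), `frame_indices` (into the recording), `stride`,
#'   `fps`, `pixel_size_um`.
#' @export
sample_clip <- function(recording, duration_s, T = 11L, start = 1L) {
  if (T %% 2L == 0L) stop("T must be odd")
  n_total <- dim(recording$frames)[3L]
  span <- as.integer(round(duration_s * recording$fps))
  stride <- span / (T - 1L)
  if (abs(stride - round(stride)) > 1e-9)
    stop("duration does not divide into T-1 uniform strides at this fps")
  stride <- as.integer(round(stride))
  idx <- start + stride * (0:(T - 1L))
  if (max(idx) > n_total) stop("recording too short for requested clip")
  central <- ((T - 3L) %/% 2L + 1L):((T - 3L) %/% 2L + 3L)
  ann <- lapply(central, function(k) recording$skeletons[[idx[k]]])
  structure(list(frames = recording$frames[, , idx, drop = FALSE],
                 annotations = ann, central = central, frame_indices = idx,
                 stride = stride, fps = recording$fps,
                 pixel_size_um = recording$pixel_size_um,
                 background_subtracted = FALSE),
            class = "worm_clip")
}

#' Subtract a background image from every frame of a clip
#' @param clip a `worm_clip`.
#' @param background H x W matrix.
#' @return The clip with residual frames and `background_subtracted = TRUE`.
#' @export
subtract_clip_background <- function(clip, background) {
  clip$frames <- sweep(clip$frames, c(1L, 2L), background)
  clip$background_subtracted <- TRUE
  clip
}

#' Synthesise overlapping-worm clips by pairing and stacking
#'
#' Randomly pairs the single-worm clips in the pool and combines each pair
#' into one clip: frames are merged pixelwise by the darkest value (worms are
#' darker than the subtracted background, so the minimum mimics optical
#' occlusion) and annotations are the union of both inputs'. Reshuffling with
#' a fresh seed yields different pairings, which is how training-epoch
#' diversity is produced. A pool of `2n` (or `2n + 1`) clips yields `n`
#' stacked clips.
#'
#' @param clip_pool list of `worm_clip`s, background-subtracted, one worm each.
#' @param seed RNG seed controlling the pairing.
#' @return list of stacked `worm_clip`s, length `floor(length(pool) / 2)`.
#' @export
synthesize_overlaps <- function(clip_pool, seed) {
  if (length(clip_pool) < 2L) stop("need at least 2 clips to pair")
  set.seed(seed)
  ord <- sample.int(length(clip_pool))
  n_pairs <- length(clip_pool) %/% 2L
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- clip_pool[[ord[2L * p - 1L]]]
    b <- clip_pool[[ord[2L * p]]]
    if (!isTRUE(a$background_subtracted) || !isTRUE(b$background_subtracted))
      stop("clips must be background-subtracted before stacking")
    if (!identical(dim(a$frames), dim(b$frames)))
      stop("pool clips must share frame geometry")
    stacked <- a
    stacked$frames <- pmin(a$frames, b$frames)
    stacked$annotations <- lapply(seq_along(a$annotations), function(k) {
      aa <- a$annotations[[k]]; bb <- b$annotations[[k]]
      names(aa) <- paste0("a_", names(aa))
      names(bb) <- paste0("b_", names(bb))
      c(aa, bb)
    })
    stacked$pair <- c(ord[2L * p - 1L], ord[2L * p])
    out[[p]] <- stacked
  }
  out
}

#' Generate a set of background-subtracted single-worm training clips
#'
#' Convenience wrapper used by the mini-training contract and the tests: runs
#' short single-worm simulations, samples one clip from each, and subtracts
#' the (known) static background.
#'
#' @param n_clips number of clips.
#' @param dim frame size (default 64 x 64 for desk-scale work).
#' @param worm_length worm length in px (default 26, scaled to the small frame).
#' @param duration_s window per clip (default 2 s).
#' @param n_points skeleton points (default 25 at this scale).
#' @param seed base RNG seed; clip i uses seed + i.
#' @param ... further arguments to [simulate_recording()].
#' @return list of `worm_clip`s with ground truth.
#' @export
simulate_clip_set <- function(n_clips, dim = c(64L, 64L), worm_length = 26,
                              duration_s = 2, n_points = 25L, seed = 1L, ...) {
  bg <- make_background(dim, n_eggs = 4L, seed = seed)
  lapply(seq_len(n_clips), function(i) {
    # one extra frame so the strided 11-frame window fits exactly
    rec <- simulate_recording(1L, duration_s = duration_s + 1 / 25, dim = dim,
                              worm_length = worm_length, n_points = n_points,
                              worm_width = 3, background = bg,
                              seed = seed + i, ...)
    subtract_clip_background(sample_clip(rec, duration_s), bg)
  })
}
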