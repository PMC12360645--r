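# Grid-cell (YOLO-style) skeleton prediction contract. A padded H x W image
# is divided into square cells (16 px by default); each cell carries K slots,
# each slot a confidence, an L-dimensional latent vector, and D shape-space
# coefficients for each of the 3 annotated central frames. For a 512 x 512
# input this is a 32 x 32 grid: coefficients (32, 32, 8, 3, 72), confidences
# (32, 32, 8), latents (32, 32, 8, 8). Training targets assign a worm to every
# cell whose centre lies within a cutoff (48 px) of the worm's central-frame
# centroid; decoding inverts the encoding for every slot above a confidence
# threshold and duplicate predictions are removed by non-maximum suppression.

#' Pad an image (or frame stack) to a multiple of m
#'
#' Pads the bottom and right edges with zeros (the background-subtracted
#' convention) so both spatial dimensions are multiples of `m`. Because
#' padding is bottom/right only, pixel coordinates are unchanged and
#' detections decoded from the padded image already live in original
#' coordinates; the original size is recorded for bounds checks.
#'
#' @param image H x W matrix or H x W x T array.
#' @param m required multiple (default 16).
#' @return list with `image` (padded), `original_dim` c(H, W), `pad`
#'   c(bottom, right).
#' @export
pad_to_multiple <- function(image, m = 16L) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("image must be a matrix or array")
  H <- d[1L]; W <- d[2L]
  Hp <- as.integer(ceiling(H / m) * m); Wp <- as.integer(ceiling(W / m) * m)
  if (length(d) == 2L) {
    out <- matrix(0, Hp, Wp); out[1:H, 1:W] <- image
  } else {
    out <- array(0, c(Hp, Wp, d[3L])); out[1:H, 1:W, ] <- image
  }
  list(image = out, original_dim = c(H, W), pad = c(Hp - H, Wp - W))
}

#' Grid geometry for a padded image
#' @param dim c(H, W) of the padded image (each a multiple of `cell_size`).
#' @param cell_size cell side in px (default 16).
#' @return list with `g_rows`, `g_cols`, `cell_size`, and matrices
#'   `centre_x`, `centre_y` (g_rows x g_cols, 0-based pixel coordinates).
#' @export
grid_geometry <- function(dim, cell_size = 16L) {
  H <- dim[1L]; W <- dim[2L]
  if (H %% cell_size != 0L || W %% cell_size != 0L)
    stop("padded image dimensions must be multiples of the cell size")
  gr <- H %/% cell_size; gc <- W %/% cell_size
  cx <- (seq_len(gc) - 1L) * cell_size + (cell_size - 1) / 2
  cy <- (seq_len(gr) - 1L) * cell_size + (cell_size - 1) / 2
  list(g_rows = gr, g_cols = gc, cell_size = as.integer(cell_size),
       centre_x = matrix(cx, gr, gc, byrow = TRUE),
       centre_y = matrix(cy, gr, gc))
}

new_prediction_grid <- function(geom, K, D, L) {
  structure(list(
    coeffs = array(0, c(geom$g_rows, geom$g_cols, K, 3L, D)),
    confidence = array(0, c(geom$g_rows, geom$g_cols, K)),
    latent = array(0, c(geom$g_rows, geom$g_cols, K, L)),
    geometry = geom, K = as.integer(K), D = as.integer(D), L = as.integer(L)),
    class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("prediction_grid: %d x %d cells (%d px), K = %d, D = %d, L = %d\n",
              g$g_rows, g$g_cols, g$cell_size, x$K, x$D, x$L))
  invisible(x)
}

#' Build training target tensors from clip annotations
#'
#' Assigns each annotated worm to every grid cell whose centre lies within
#' `cutoff` pixels of the worm's central-frame centroid (nearest worms first,
#' at most `K` per cell, warning on overflow). Assigned slots carry the
#' skeleton's shape-space coefficients for each of the three central frames,
#' encoded relative to the cell centre, and a confidence target of 1; all
#' other slots are 0.
#'
#' @param annotations list of 3 named lists (worm id -> skeleton), as stored
#'   in a `worm_clip`. Worm ids must be common across the three frames.
#' @param space a `shape_space` whose N matches the annotation skeletons.
#' @param dim c(H, W) of the (padded) clip frames.
#' @param cell_size grid cell side (default 16).
#' @param cutoff assignment radius in px (default 48).
#' @param K slots per cell (default 8).
#' @param L latent dimension carried by the grid (default 8; targets zero).
#' @return a `prediction_grid` with an extra `worm_ids` array (g x g x K,
#'   character NA where unassigned).
#' @export
assign_targets <- function(annotations, space, dim, cell_size = 16L,
                           cutoff = 48, K = 8L, L = 8L) {
  if (length(annotations) != 3L) stop("annotations must cover 3 central frames")
  geom <- grid_geometry(dim, cell_size)
  grid <- new_prediction_grid(geom, K, space$D, L)
  grid$worm_ids <- array(NA_character_, c(geom$g_rows, geom$g_cols, K))
  ids <- names(annotations[[2L]])
  if (length(ids) == 0L) return(grid)
  cent <- t(vapply(ids, function(id) skeleton_centroid(annotations[[2L]][[id]]),
                   numeric(2L)))
  overflow <- 0L
  for (r in seq_len(geom$g_rows)) for (c in seq_len(geom$g_cols)) {
    dx <- cent[, 1L] - geom$centre_x[r, c]
    dy <- cent[, 2L] - geom$centre_y[r, c]
    dist <- sqrt(dx^2 + dy^2)
    near <- which(dist <= cutoff)
    if (length(near) == 0L) next
    near <- near[order(dist[near], ids[near])]   # nearest first, id tie-break
    if (length(near) > K) { overflow <- overflow + 1L; near <- near[1:K] }
    for (k in seq_along(near)) {
      id <- ids[near[k]]
      off <- c(geom$centre_x[r, c], geom$centre_y[r, c])
      for (f in 1:3) {
        sk <- annotations[[f]][[id]]
        if (is.null(sk)) stop(sprintf("worm %s missing in central frame %d", id, f))
        grid$coeffs[r, c, k, f, ] <- encode_skeleton(sk, space, off)
      }
      grid$confidence[r, c, k] <- 1
      grid$worm_ids[r, c, k] <- id
    }
  }
  if (overflow > 0L)
    warning(sprintf("%d cell(s) had more than K worms within the cutoff; kept the K nearest", overflow))
  grid
}

#' Decode a prediction grid into per-frame detections
#'
#' Every slot with confidence strictly above `conf_threshold` is decoded:
#' coefficients times the PCA basis plus the mean shape, offset by the cell
#' centre, yielding one skeleton per annotated central frame.
#'
#' @param grid a `prediction_grid`.
#' @param space the `shape_space` used for encoding (D must match).
#' @param conf_threshold decoding confidence threshold (default 0.5).
#' @param frames frame labels for the 3 central frames (default 1:3).
#' @return list of detections; each is a list with `skeleton`, `confidence`,
#'   `latent`, `frame`, `cell` c(row, col), `slot`.
#' @export
decode_grid <- function(grid, space, conf_threshold = 0.5, frames = 1:3) {
  if (grid$D != space$D) stop("grid D does not match shape space D")
  geom <- grid$geometry
  hits <- which(grid$confidence > conf_threshold, arr.ind = TRUE)
  out <- vector("list", nrow(hits) * 3L)
  n <- 0L
  if (nrow(hits) > 0L) for (h in seq_len(nrow(hits))) {
    r <- hits[h, 1L]; c <- hits[h, 2L]; k <- hits[h, 3L]
    off <- c(geom$centre_x[r, c], geom$centre_y[r, c])
    for (f in 1:3) {
      n <- n + 1L
      out[[n]] <- list(
        skeleton = decode_skeleton(grid$coeffs[r, c, k, f, ], space, off),
        confidence = grid$confidence[r, c, k],
        latent = grid$latent[r, c, k, ],
        frame = frames[f], cell = c(r, c), slot = k)
    }
  }
  out[seq_len(n)]
}

# orientation-minimised mean point-to-point distance between two skeletons
mean_point_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (nrow(a) != nrow(b)) {
    n <- max(nrow(a), nrow(b))
    a <- unclass(resample_equal_arclength(a, n))
    b <- unclass(resample_equal_arclength(b, n))
  }
  fwd <- mean(sqrt(rowSums((a - b)^2)))
  rev_ <- mean(sqrt(rowSums((a - b[rev(seq_len(nrow(b))), ])^2)))
  min(fwd, rev_)
}

#' Suppress duplicate detections (greedy non-maximum suppression)
#'
#' Detections from one frame are sorted by confidence; a detection is dropped
#' when its orientation-minimised mean point-to-point distance to an already
#' kept detection is below `min_separation`.
#'
#' @param detections list of detections (as from [decode_grid()]), one frame.
#' @param min_separation suppression radius in px (default 12).
#' @return the surviving detections, confidence-sorted.
#' @export
deduplicate <- function(detections, min_separation = 12) {
  if (length(detections) <= 1L) return(detections)
  ord <- order(-vapply(detections, `[[`, numeric(1L), "confidence"))
  kept <- list()
  for (i in ord) {
    d <- detections[[i]]
    dup <- any(vapply(kept, function(k)
      mean_point_distance(k$skeleton, d$skeleton) < min_separation, logical(1L)))
    if (!dup) kept[[length(kept) + 1L]] <- d
  }
  kept
}
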