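# Shared I/O. The environment offers no HDF5/TIFF bindings, so stacks are
# stored either as RDS (compact, runtime artifacts) or as a plain-text stack
# format, and skeleton/detection tables as CSV written at full double
# precision (%.17g) so write -> read round trips are lossless. All
# coordinates are 0-based with x = column, y = row, origin top-left; every
# text file states this in a header comment.

COORD_HEADER <- "# nematrack table; coordinates 0-based, x = column, y = row, origin top-left"

#' Write a video stack
#'
#' `.rds` gives a compact binary stack; any other extension writes the
#' plain-text stack format (`nematrack-stack H W T` header, then one line of
#' %.17g pixel values per frame, column-major).
#'
#' @param video H x W x T array.
#' @param path output file.
#' @export
write_video <- function(video, path) {
  d <- dim(video)
  if (is.null(d) || length(d) != 3L) stop("video must be an H x W x T array")
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(video, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("nematrack-stack %d %d %d", d[1L], d[2L], d[3L]), con)
    for (t in seq_len(d[3L]))
      writeLines(paste(sprintf("%.17g", video[, , t]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a video stack written by [write_video()]
#' @param path input file (.rds or text stack).
#' @return H x W x T array.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop(sprintf("video file not found: %s", path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    v <- readRDS(path)
    if (length(dim(v)) != 3L) stop("RDS file does not hold an H x W x T array")
    return(v)
  }
  con <- file(path, "r"); on.exit(close(con))
  hdr <- strsplit(readLines(con, n = 1L), " ")[[1L]]
  if (length(hdr) != 4L || hdr[1L] != "nematrack-stack")
    stop(sprintf("%s: not a nematrack text stack (bad header)", path))
  d <- as.integer(hdr[2:4])
  out <- array(0, d)
  for (t in seq_len(d[3L])) {
    vals <- as.numeric(strsplit(readLines(con, n = 1L), " ")[[1L]])
    if (length(vals) != d[1L] * d[2L])
      stop(sprintf("%s: frame %d has %d values, expected %d", path, t,
                   length(vals), d[1L] * d[2L]))
    out[, , t] <- vals
  }
  out
}

#' Flatten per-frame skeleton annotations to a long table
#'
#' @param skeletons length-T list, each a named list worm id -> skeleton
#'   (the `skeletons` field of a `worm_recording`).
#' @param frames frame indices (default seq_along).
#' @return data.frame with frame, worm_id, point_index (0-based), x, y.
#' @export
skeletons_to_table <- function(skeletons, frames = seq_along(skeletons)) {
  rows <- list()
  for (i in seq_along(skeletons)) {
    for (id in names(skeletons[[i]])) {
      s <- unclass(skeletons[[i]][[id]])
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frames[i], worm_id = id,
        point_index = seq_len(nrow(s)) - 1L, x = s[, 1L], y = s[, 2L])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), worm_id = character(0),
                      point_index = integer(0), x = numeric(0), y = numeric(0)))
  do.call(rbind, rows)
}

#' Rebuild per-frame skeleton lists from a long table
#' @param df table as produced by [skeletons_to_table()].
#' @return named list: frame -> named list worm id -> skeleton.
#' @export
table_to_skeletons <- function(df) {
  out <- list()
  for (f in sort(unique(df$frame))) {
    sub <- df[df$frame == f, , drop = FALSE]
    ann <- list()
    for (id in unique(sub$worm_id)) {
      w <- sub[sub$worm_id == id, , drop = FALSE]
      w <- w[order(w$point_index), , drop = FALSE]
      ann[[as.character(id)]] <- as_skeleton(cbind(x = w$x, y = w$y))
    }
    out[[as.character(f)]] <- ann
  }
  out
}

#' Write a skeleton/detection table as CSV (lossless)
#'
#' @param df data.frame (frame, worm_id, point_index, x, y, optional extras).
#' @param path output CSV.
#' @export
write_skeleton_table <- function(df, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(COORD_HEADER, con)
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a skeleton/detection table CSV
#' @param path CSV written by [write_skeleton_table()].
#' @return data.frame with numeric columns restored.
#' @export
read_skeleton_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required columns (%s)", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' Persist a shape space as JSON
#' @param space `shape_space`.
#' @param path output path.
#' @export
save_shape_space <- function(space, path) {
  jsonlite::write_json(list(mean = space$mean, basis = space$basis,
                            sdev = space$sdev, N = space$N, D = space$D),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Load a shape space saved by [save_shape_space()]
#' @param path JSON path.
#' @return `shape_space`.
#' @export
load_shape_space <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), basis = as.matrix(x$basis),
                 sdev = as.numeric(x$sdev), N = as.integer(x$N),
                 D = as.integer(x$D)),
            class = "shape_space")
}

#' Default run configuration
#'
#' All pipeline tunables in one place: decoding confidence threshold 0.5,
#' assignment cutoff 48 px, cell size 16 px, shape-space dimension 72, K = 8
#' slots, latent dimension 8, 11-frame clips, 1:400 background subsampling,
#' 1:3 inference downsampling, 25 fps, 12.4 um/px, 49 skeleton points.
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(conf_threshold = 0.5, cutoff = 48, cell_size = 16L, D = 72L,
                 K = 8L, L = 8L, T = 11L, subsample_step = 400L,
                 downsample = 3L, fps = 25, pixel_size_um = 12.4,
                 n_points = 49L, max_gap = 12L, min_separation = 12,
                 w_spatial = 1, w_latent = 1),
            class = "run_config")
}

validate_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1L))
  if (any(unlist(cfg[num]) <= 0)) stop("config values must be positive")
  if (cfg$D > 2L * cfg$n_points) stop("config invalid: D exceeds 2N")
  if (cfg$T %% 2L == 0L) stop("config invalid: T must be odd")
  cfg
}

#' Save / load a run configuration as JSON
#' @param cfg `run_config` list.
#' @param path JSON path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(validate_config(cfg)), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_config()), x)
  for (f in c("cell_size", "D", "K", "L", "T", "subsample_step", "downsample",
              "n_points", "max_gap"))
    cfg[[f]] <- as.integer(cfg[[f]])
  structure(validate_config(cfg), class = "run_config")
}
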