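#' Apply per-channel gains to a frame sequence
#'
#' Emulates on-sensor amplification into the stored 8-bit frame: each pixel
#' channel is multiplied by its gain, rounded half-up to an integer, and
#' clipped to the representable range. With gains `(1, 3, 18)` a pixel
#' `(100, 50, 20)` becomes `(100, 150, 255)` - the blue product 360
#' saturates.
#'
#' @param frames a [frame_sequence()].
#' @param gains positive per-channel multipliers (red, green, blue).
#' @return A [frame_sequence()] with amplified pixels.
#' @export
apply_gains <- function(frames, gains) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(gains) != 3 || any(!is.finite(gains)) || any(gains <= 0)) {
    stop("gains must be 3 positive numbers")
  }
  maxv <- 2^(frames$metadata$bit_depth %||% 8) - 1
  g <- rep(gains, each = prod(dim(frames$frames[[1]])[1:2]))
  out <- lapply(frames$frames, function(fr) {
    arr <- clamp(round_half_up(as.numeric(fr) * g), 0, maxv)
    dim(arr) <- dim(fr)
    storage.mode(arr) <- "integer"
    arr
  })
  meta <- frames$metadata
  meta$gains <- (meta$gains %||% c(1, 1, 1)) * gains
  frame_sequence(out, frames$fps, meta)
}

#' Extract a PPG trace from camera frames
#'
#' Computes the spatial mean of each color channel over the entirety of each
#' frame (no sub-region selection), yielding the 3 x n channel-by-frame
#' matrix that all downstream analysis consumes.
#'
#' @param frames a [frame_sequence()] with at least one frame.
#' @return A [ppg_record()].
#' @export
extract_ppg <- function(frames) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(frames$frames) == 0) stop("empty frame sequence")
  vals <- vapply(frames$frames,
                 function(fr) colMeans(matrix(as.numeric(fr), ncol = 3)),
                 numeric(3))
  ppg_record(matrix(vals, nrow = 3), frames$fps,
             subject_id = frames$metadata$subject_id %||% "unknown",
             hand = frames$metadata$hand %||% "left")
}

#' Report per-channel clipping
#'
#' Fraction of samples stuck at the bottom (0) or top (2^bits - 1) of the
#' representable range, per channel. Saturation destroys the pulsatile
#' information a channel carries, so any channel exceeding
#' `threshold_fraction` raises a warning flag in the returned report.
#'
#' @param x a [frame_sequence()] (pixel-level fractions) or [ppg_record()]
#'   (trace-level fractions; a trace sample counts as clipped when it sits at
#'   a range end within 0.5).
#' @param threshold_fraction flag threshold (default 0.01).
#' @param max_value top of the representable range (default 255).
#' @return List with `fraction` (named per-channel), `flagged` (logical per
#'   channel) and `any_flagged`.
#' @export
detect_clipping <- function(x, threshold_fraction = 0.01, max_value = 255) {
  if (inherits(x, "frame_sequence")) {
    maxv <- 2^(x$metadata$bit_depth %||% 8) - 1
    tot <- 0
    clipped <- c(0, 0, 0)
    for (fr in x$frames) {
      m <- matrix(as.numeric(fr), ncol = 3)
      clipped <- clipped + colSums(m <= 0 | m >= maxv)
      tot <- tot + nrow(m)
    }
    frac <- clipped / tot
  } else if (inherits(x, "ppg_record")) {
    frac <- rowMeans(x$values <= 0.5 | x$values >= max_value - 0.5)
  } else {
    stop("x must be a frame_sequence or ppg_record")
  }
  names(frac) <- c("red", "green", "blue")
  flagged <- frac > threshold_fraction
  list(fraction = frac, flagged = flagged, any_flagged = any(flagged))
}

#' Write a frame sequence to a directory of PNG images
#'
#' Frames are written as `frame_000000.png`, `frame_000001.png`, ... with a
#' `frames.json` sidecar holding fps, gains and bit depth, so that real
#' captures decoded to frames and synthetic renders share one on-disk format.
#'
#' @param frames a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(inherits(frames, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- 2^(frames$metadata$bit_depth %||% 8) - 1
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / maxv,
                  file.path(dir, sprintf("frame_%06d.png", i - 1)))
  }
  meta <- frames$metadata
  meta$fps <- frames$fps
  meta$n_frames <- length(frames$frames)
  jsonlite::write_json(meta, file.path(dir, "frames.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a frame sequence from a directory of PNG images
#'
#' @param dir directory produced by [write_frames()] (or real frames decoded
#'   into the same layout).
#' @return A [frame_sequence()].
#' @export
read_frames <- function(dir) {
  meta_path <- file.path(dir, "frames.json")
  if (!file.exists(meta_path)) stop("missing frames.json sidecar in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no frame_*.png files in ", dir)
  maxv <- 2^(meta$bit_depth %||% 8) - 1
  frames <- lapply(files, function(f) {
    arr <- png::readPNG(f) * maxv
    arr <- round_half_up(arr)
    storage.mode(arr) <- "integer"
    arr
  })
  frame_sequence(frames, meta$fps, as.list(meta))
}
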