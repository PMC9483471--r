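#' Construct a PPG record
#'
#' @param values 3 x n matrix of channel means (rows red, green, blue) on the
#'   8-bit scale (continuous; quantization only happens in the frame domain).
#' @param fps sampling rate in frames per second.
#' @param subject_id,hand record identity.
#' @return List of class `ppg_record`.
#' @export
ppg_record <- function(values, fps, subject_id = "s1", hand = "left") {
  stopifnot(is.matrix(values), nrow(values) == 3, fps > 0)
  rownames(values) <- c("red", "green", "blue")
  structure(list(values = values, fps = fps,
                 subject_id = as.character(subject_id), hand = hand),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s (%s hand): %d frames at %g fps (%.1f s)\n",
              x$subject_id, x$hand, ncol(x$values), x$fps,
              ncol(x$values) / x$fps))
  invisible(x)
}

#' Synthesize a three-channel PPG trace from an SpO2 trajectory
#'
#' The forward optical model. For channel `c` with gain `g_c`, baseline
#' `DC_c` (8-bit scale) and zero-mean pulse waveform `w(t)`:
#'
#' `s_c(t) = g_c * (DC_c * (1 + dc_offset) - AC_c(S(t)) * (1 - callus) * w(t)) + noise`
#'
#' with `AC_c(S) = DC_c * pulsatility * mu_c(S) / mu_ref` so that the
#' pulsatile fraction is proportional to the blood's effective absorption
#' (see [optical_model()]). The pulse enters with a negative sign: a systolic
#' blood-volume surge absorbs more light, so reflectance dips. The 1 Hz SpO2
#' trajectory is linearly interpolated to the frame clock. Output values are
#' continuous (pre-quantization); gain-driven overflow is permitted here and
#' surfaces as clipping once frames are rendered.
#'
#' @param trace an [oximeter_trace()] (1 Hz ground truth).
#' @param profile a [subject_profile()].
#' @param camera a [camera_model()].
#' @return A [ppg_record()] sampled at `camera$fps` covering the trace
#'   duration.
#' @export
synthesize_ppg <- function(trace, profile, camera) {
  stopifnot(inherits(trace, "oximeter_trace"),
            inherits(profile, "subject_profile"),
            inherits(camera, "camera_model"))
  opt <- profile$optical
  duration <- max(trace$time_s) + 1          # trace covers [0, duration)
  n <- round(duration * camera$fps)
  t <- (seq_len(n) - 1) / camera$fps
  S <- if (nrow(trace) == 1) {
    rep(trace$spo2, n) / 100
  } else {
    stats::approx(trace$time_s, trace$spo2, xout = t, rule = 2)$y / 100
  }

  phase <- profile$phase + t * opt$heart_rate_bpm / 60
  w <- ppg_waveform(phase, opt$waveform_params, zero_mean = TRUE)

  mu <- effective_absorption(S, opt)          # n x 3
  mu_ref <- absorption_normalizer(opt)
  dc8 <- opt$dc_level * (2^camera$bit_depth - 1)

  vals <- matrix(0, 3, n)
  noise <- with_seed(profile$seed, {
    matrix(stats::rnorm(3L * n), 3, n) * opt$noise_sd
  })
  for (c_i in 1:3) {
    ac <- dc8[c_i] * opt$pulsatility * mu[, c_i] / mu_ref
    vals[c_i, ] <- camera$gains[c_i] *
      (dc8[c_i] * (1 + profile$dc_offset_factor) -
         ac * (1 - profile$callus_factor) * w) + noise[c_i, ]
  }
  ppg_record(vals, camera$fps, profile$subject_id, profile$hand)
}

#' Construct a frame sequence
#'
#' @param frames list of `height x width x 3` integer arrays (stored pixel
#'   values).
#' @param fps frames per second.
#' @param metadata list of capture settings (gains, bit depth, ...).
#' @return List of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, metadata = list()) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  stopifnot(length(d) == 3, d[3] == 3)
  structure(list(frames = frames, fps = fps, metadata = metadata),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d px at %g fps\n",
              length(x$frames), d[2], d[1], x$fps))
  invisible(x)
}

#' Render a PPG trace into camera frames
#'
#' Each frame's pixels are drawn as the instantaneous channel value plus
#' i.i.d. Gaussian spatial noise, rounded half-up to integers and clipped to
#' the representable range. With zero spatial noise a frame is simply the
#' quantized trace value replicated over the sensor.
#'
#' @param ppg a [ppg_record()] sampled at `camera$fps`.
#' @param camera a [camera_model()].
#' @param seed integer seed for the spatial noise.
#' @return A [frame_sequence()] with one frame per trace sample.
#' @export
synthesize_frames <- function(ppg, camera, seed = 1L) {
  stopifnot(inherits(ppg, "ppg_record"), inherits(camera, "camera_model"))
  if (abs(ppg$fps - camera$fps) > 1e-9) {
    stop("ppg must be sampled at the camera frame rate")
  }
  w <- camera$resolution[1]
  h <- camera$resolution[2]
  if (w < 1 || h < 1) stop("camera resolution must be at least 1x1 pixels")
  n <- ncol(ppg$values)
  npix <- w * h
  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      px <- rep(ppg$values[, i], each = npix)
      if (camera$spatial_noise_sd > 0) {
        px <- px + stats::rnorm(3L * npix, sd = camera$spatial_noise_sd)
      }
      arr <- array(clamp(round_half_up(px), 0, camera$max_value), dim = c(h, w, 3))
      storage.mode(arr) <- "integer"
      arr
    })
  })
  frame_sequence(frames, camera$fps,
                 metadata = list(fps = camera$fps, gains = camera$gains,
                                 bit_depth = camera$bit_depth,
                                 subject_id = ppg$subject_id, hand = ppg$hand))
}
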