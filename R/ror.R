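#' Ratio-of-ratios configuration
#'
#' Coefficients and settings for the classical two-wavelength Beer-Lambert
#' inversion. Only the red and green effective wavelengths enter the
#' inversion; blue participates through the channel-range calibration
#' features. Defaults share the extinction coefficients of
#' [optical_model()], so the inversion is the exact inverse of the
#' package's forward synthesis.
#'
#' @param eps_hbo2,eps_hb length-2 extinction coefficients `(red, green)`.
#' @param min_beats_per_window minimum complete beats required in a window
#'   before it is considered stable (default 2).
#' @param nominal_hr_bpm nominal heart rate used to set the minimum peak
#'   separation (default 70).
#' @param dc_scope `"beats"` (default) computes the DC level over the span
#'   of complete beats - an integer number of cardiac periods, so the
#'   zero-mean pulse cannot bias it - or `"window"` for the plain window
#'   mean.
#' @return List of class `ror_config`.
#' @export
ror_config <- function(eps_hbo2 = c(red = 319.6, green = 39956.8),
                       eps_hb = c(red = 3226.6, green = 39036.4),
                       min_beats_per_window = 2,
                       nominal_hr_bpm = 70,
                       dc_scope = c("beats", "window")) {
  stopifnot(length(eps_hbo2) == 2, length(eps_hb) == 2,
            all(eps_hbo2 > 0), all(eps_hb > 0), min_beats_per_window >= 1,
            nominal_hr_bpm > 0)
  dc_scope <- match.arg(dc_scope)
  structure(list(eps_hbo2 = unname(eps_hbo2), eps_hb = unname(eps_hb),
                 min_beats_per_window = min_beats_per_window,
                 nominal_hr_bpm = nominal_hr_bpm, dc_scope = dc_scope),
            class = "ror_config")
}

# Local maxima of `x` with a minimum topographic prominence and minimum
# index separation. When two peaks are closer than min_sep the higher one
# wins. Returns sorted indices.
find_peaks <- function(x, min_prominence = 0, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    p <- cand[j]
    # prominence: height above the higher of the two saddle minima reached
    # before a taller sample is met on each side
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > x[p])
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1):(p - 1)])
    right <- x[(p + 1):n]
    higher_r <- which(right > x[p])
    rmax <- if (length(higher_r)) p + min(higher_r) else n
    rmin <- min(x[(p + 1):rmax])
    keep[j] <- (x[p] - max(lmin, rmin)) >= min_prominence
  }
  cand <- cand[keep]
  if (length(cand) <= 1 || min_sep <= 1) return(cand)
  ord <- cand[order(-x[cand])]
  chosen <- integer(0)
  for (p in ord) {
    if (all(abs(chosen - p) >= min_sep)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Segment cardiac beats in a PPG window
#'
#' The camera pulse is a reflectance dip (systole absorbs light), so beats
#' are detected on the inverted signal: "systolic peak height" is the depth
#' of the dip below the surrounding diastolic baseline. Peaks require a
#' prominence of at least 0.3 times the window's inter-quartile range and a
#' separation of at least 0.4 nominal beat periods. Beats are delimited by
#' the diastolic minima between consecutive peaks; partial beats truncated
#' by the window edge are dropped.
#'
#' @param window `time x 3` matrix of channel values (or a plain numeric
#'   vector treated as one channel).
#' @param channel channel used for detection: `"red"`, `"green"` (default;
#'   strongest pulsatile signal) or `"blue"`.
#' @param fps sampling rate of the window.
#' @param config a [ror_config()].
#' @return Data frame of complete beats with columns `start`, `peak`, `end`
#'   (frame indices), `height` (units above beat baseline, on the inverted
#'   signal) and `upslope` (max rise per frame toward the peak). Zero rows
#'   for flat or unstable signal.
#' @export
segment_beats <- function(window, channel = "green", fps = 30,
                          config = ror_config()) {
  x <- if (is.matrix(window)) {
    window[, match(channel, c("red", "green", "blue"))]
  } else {
    as.numeric(window)
  }
  if (length(x) < fps) stop("window must cover at least 1 s of signal")
  inv <- -x
  iqr <- stats::IQR(inv)
  if (iqr < 1e-12) return(empty_beats())
  min_sep <- max(1, floor(0.4 * fps * 60 / config$nominal_hr_bpm))
  peaks <- find_peaks(inv, min_prominence = 0.3 * iqr, min_sep = min_sep)
  if (length(peaks) < 1) return(empty_beats())
  # diastolic minima between consecutive systolic peaks delimit the beats;
  # a leading (trailing) trough is also accepted when the minimum before the
  # first (after the last) peak lies strictly inside the window - a minimum
  # sitting on the window edge belongs to a truncated beat and is dropped
  n_t <- length(x)
  troughs <- integer(0)
  if (length(peaks) >= 1) {
    seg <- 1:peaks[1]
    lead <- seg[which.min(inv[seg])]
    if (lead > 1 && lead < peaks[1]) troughs <- lead
  }
  if (length(peaks) >= 2) {
    troughs <- c(troughs, vapply(seq_len(length(peaks) - 1), function(j) {
      seg <- peaks[j]:peaks[j + 1]
      seg[which.min(inv[seg])]
    }, integer(1)))
  }
  seg <- peaks[length(peaks)]:n_t
  trail <- seg[which.min(inv[seg])]
  if (trail < n_t && trail > peaks[length(peaks)]) troughs <- c(troughs, trail)
  if (length(troughs) < 2) return(empty_beats())
  beats <- data.frame(start = troughs[-length(troughs)],
                      end = troughs[-1])
  beats$peak <- mapply(function(s, e) {
    seg <- s:e
    seg[which.max(inv[seg])]
  }, beats$start, beats$end)
  beats$height <- inv[beats$peak] - (inv[beats$start] + inv[beats$end]) / 2
  beats$upslope <- mapply(function(s, p) {
    if (p <= s) return(NA_real_)
    max(diff(inv[s:p]))
  }, beats$start, beats$peak)
  beats[beats$height > 0, c("start", "peak", "end", "height", "upslope")]
}

empty_beats <- function() {
  data.frame(start = integer(0), peak = integer(0), end = integer(0),
             height = numeric(0), upslope = numeric(0))
}

# Per-channel AC/DC features of one window, using a common beat segmentation
# from the detection channel. AC_c = mean systolic dip depth of channel c
# over the segmented beats; DC_c = mean level (over complete beats or the
# whole window, per config$dc_scope); upslope kept as auxiliary feature.
window_acdc <- function(window, fps, config, detect_channel = "green") {
  beats <- segment_beats(window, channel = detect_channel, fps = fps,
                         config = config)
  if (nrow(beats) < config$min_beats_per_window) return(NULL)
  span <- beats$start[1]:beats$end[nrow(beats)]
  out <- list(n_beats = nrow(beats))
  for (c_i in 1:3) {
    ch <- c("red", "green", "blue")[c_i]
    inv <- -window[, c_i]
    peak_idx <- vapply(seq_len(nrow(beats)), function(j) {
      seg <- beats$start[j]:beats$end[j]
      seg[which.max(inv[seg])]
    }, integer(1))
    heights <- inv[peak_idx] - (inv[beats$start] + inv[beats$end]) / 2
    upslopes <- vapply(seq_len(nrow(beats)), function(j) {
      if (peak_idx[j] <= beats$start[j]) return(NA_real_)
      max(diff(inv[beats$start[j]:peak_idx[j]]))
    }, numeric(1))
    dc <- if (config$dc_scope == "beats") mean(window[span, c_i]) else mean(window[, c_i])
    out[[paste0("ac_", ch)]] <- mean(heights)
    out[[paste0("dc_", ch)]] <- dc
    out[[paste0("upslope_", ch)]] <- mean(upslopes, na.rm = TRUE)
  }
  out
}

#' Ratio of ratios of one window
#'
#' `R = (AC_red / DC_red) / (AC_green / DC_green)` with AC the average
#' systolic dip depth over the window's complete beats and DC the mean
#' channel level (see [ror_config()] for the DC scope). Windows with fewer
#' than `min_beats_per_window` complete beats are unstable and return `NA`
#' with an attribute naming the reason.
#'
#' @param window `time x 3` matrix.
#' @param config a [ror_config()].
#' @param fps sampling rate.
#' @return Unitless ratio, or `NA` (attribute `reason = "unstable"`).
#' @export
window_ror <- function(window, config = ror_config(), fps = 30) {
  f <- window_acdc(window, fps, config)
  if (is.null(f) || f$ac_green <= 0 || f$dc_green <= 0 ||
      f$dc_red <= 0 || f$ac_red <= 0) {
    return(structure(NA_real_, reason = "unstable"))
  }
  (f$ac_red / f$dc_red) / (f$ac_green / f$dc_green)
}

#' Convert a ratio of ratios to raw SpO2
#'
#' Two-wavelength Beer-Lambert inversion at the red/green effective
#' wavelengths:
#' `S = 100 * (eps_hb_r - R * eps_hb_g) / (eps_hb_r - eps_hbo2_r + R * (eps_hbo2_g - eps_hb_g))`,
#' clamped to \[0, 100\]. `R = eps_hb_r / eps_hb_g` maps to 0% and
#' `R = eps_hbo2_r / eps_hbo2_g` to 100%.
#'
#' @param R unitless ratio(s), > 0. Vectorized.
#' @param config a [ror_config()].
#' @return Raw SpO2 in percent.
#' @export
spo2_from_ratio <- function(R, config = ror_config()) {
  er_o <- config$eps_hbo2[1]; eg_o <- config$eps_hbo2[2]
  er_d <- config$eps_hb[1];   eg_d <- config$eps_hb[2]
  denom <- (er_d - er_o) + R * (eg_o - eg_d)
  if (any(abs(denom) < 1e-9 * max(abs(c(er_d, er_o, eg_o, eg_d))), na.rm = TRUE)) {
    stop("degenerate inversion: denominator near zero for these extinction coefficients")
  }
  clamp(100 * (er_d - R * eg_d) / denom, 0, 100)
}

#' Forward map from SpO2 to the expected ratio of ratios
#'
#' The algebraic inverse of [spo2_from_ratio()]:
#' `R(S) = mu_red(S) / mu_green(S)` with
#' `mu_c(S) = eps_hbo2_c * S + eps_hb_c * (1 - S)` and `S` the saturation
#' fraction. Useful for oracle checks and for seeding calibration grids.
#'
#' @param spo2 SpO2 in percent. Vectorized.
#' @param config a [ror_config()].
#' @return Unitless ratio(s).
#' @export
spo2_to_ratio <- function(spo2, config = ror_config()) {
  S <- spo2 / 100
  (config$eps_hbo2[1] * S + config$eps_hb[1] * (1 - S)) /
    (config$eps_hbo2[2] * S + config$eps_hb[2] * (1 - S))
}

#' Per-window features for the ratio-of-ratios path
#'
#' For every window of a sample set: the raw Beer-Lambert SpO2, the
#' per-channel ranges (max - min) and mean beat upslopes, the beat count,
#' and a stability flag. Unstable windows (too few complete beats) carry NA
#' features and are excluded from calibration fitting and evaluation, with
#' counts retrievable from the `stable` column.
#'
#' @param samples a raw [sample_set()].
#' @param config a [ror_config()].
#' @param fps sampling rate of the windows.
#' @return Data frame with one row per sample.
#' @export
ror_features <- function(samples, config = ror_config(), fps = 30) {
  stopifnot(inherits(samples, "sample_set"))
  if (samples$standardized) stop("ratio-of-ratios operates on raw windows")
  n <- n_samples(samples)
  out <- data.frame(subject_id = samples$subject_id, hand = samples$hand,
                    center_time_s = samples$center_time_s,
                    truth = samples$label,
                    raw_spo2 = NA_real_, range_red = NA_real_,
                    range_green = NA_real_, range_blue = NA_real_,
                    upslope_red = NA_real_, upslope_green = NA_real_,
                    upslope_blue = NA_real_,
                    n_beats = 0L, stable = FALSE)
  for (i in seq_len(n)) {
    w <- samples$windows[i, , ]
    f <- window_acdc(w, fps, config)
    out$range_red[i] <- diff(range(w[, 1]))
    out$range_green[i] <- diff(range(w[, 2]))
    out$range_blue[i] <- diff(range(w[, 3]))
    if (is.null(f)) next
    R <- (f$ac_red / f$dc_red) / (f$ac_green / f$dc_green)
    if (!is.finite(R) || R <= 0) next
    out$raw_spo2[i] <- spo2_from_ratio(R, config)
    out$upslope_red[i] <- f$upslope_red
    out$upslope_green[i] <- f$upslope_green
    out$upslope_blue[i] <- f$upslope_blue
    out$n_beats[i] <- f$n_beats
    out$stable[i] <- TRUE
  }
  out
}

#' Fit the linear calibration of the ratio-of-ratios path
#'
#' Ordinary least squares from the calculated raw SpO2 and the RGB channel
#' ranges to the ground truth, fit on training folds only. Rank deficiency
#' aborts with a pointer at the offending features.
#'
#' @param features data frame from [ror_features()] (training rows only;
#'   unstable rows are dropped automatically).
#' @param include_slopes also include the per-channel mean upslopes as
#'   calibration features (default FALSE).
#' @return List of class `ror_calibration` with the fitted `lm` coefficients
#'   and the feature names used.
#' @export
fit_calibration <- function(features, include_slopes = FALSE) {
  d <- features[features$stable & is.finite(features$raw_spo2), , drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 stable training windows to calibrate")
  feats <- c("raw_spo2", "range_red", "range_green", "range_blue")
  if (include_slopes) feats <- c(feats, "upslope_red", "upslope_green", "upslope_blue")
  fml <- stats::as.formula(paste("truth ~", paste(feats, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient calibration design; consider removing feature(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(coefficients = stats::coef(fit), features = feats,
                 sigma = stats::sigma(fit), n = nrow(d)),
            class = "ror_calibration")
}

#' Apply a fitted calibration
#'
#' @param calibration a `ror_calibration` from [fit_calibration()].
#' @param features data frame from [ror_features()].
#' @return Numeric vector of calibrated SpO2 predictions (NA for unstable
#'   windows).
#' @export
apply_calibration <- function(calibration, features) {
  stopifnot(inherits(calibration, "ror_calibration"))
  X <- cbind(1, as.matrix(features[, calibration$features, drop = FALSE]))
  pred <- drop(X %*% calibration$coefficients)
  pred[!features$stable] <- NA_real_
  pred
}

#' Leave-one-subject-out evaluation of the ratio-of-ratios baseline
#'
#' Uses the same subject splits as [loocv_cnn()]: in each fold the
#' calibration is fit on all subjects except the test subject, then applied
#' out-of-fold. Unstable windows are excluded from both fitting and
#' evaluation; their count is logged per fold.
#'
#' @param samples a raw [sample_set()].
#' @param config a [ror_config()].
#' @param fps window sampling rate.
#' @param include_slopes forwarded to [fit_calibration()].
#' @return List of class `loocv_result` (same shape as [loocv_cnn()]'s,
#'   with `n_unstable` per fold and no `model` field; `calibration`
#'   instead).
#' @export
loocv_ror <- function(samples, config = ror_config(), fps = 30,
                      include_slopes = FALSE) {
  stopifnot(inherits(samples, "sample_set"))
  subjects <- sort(unique(samples$subject_id))
  if (length(subjects) < 3) stop("need at least 3 subjects")
  features <- ror_features(samples, config, fps)
  folds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    test_sub <- subjects[i]
    tr <- features[features$subject_id != test_sub, , drop = FALSE]
    te <- features[features$subject_id == test_sub, , drop = FALSE]
    calib <- fit_calibration(tr, include_slopes = include_slopes)
    pred <- apply_calibration(calib, te)
    ok <- is.finite(pred)
    folds[[i]] <- list(subject = test_sub,
                       pred = pred[ok], truth = te$truth[ok],
                       hand = te$hand[ok],
                       center_time_s = te$center_time_s[ok],
                       mae = mean(abs(pred[ok] - te$truth[ok])),
                       baseline_mae = mean(abs(mean(tr$truth) - te$truth[ok])),
                       n_unstable = sum(!te$stable),
                       calibration = calib)
  }
  maes <- vapply(folds, `[[`, numeric(1), "mae")
  structure(list(folds = folds, mae = mean(maes), mae_sd = stats::sd(maes),
                 baseline_mae = mean(vapply(folds, `[[`, numeric(1),
                                            "baseline_mae"))),
            class = "loocv_result")
}
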