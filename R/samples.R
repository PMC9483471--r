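#' Construct a sample set
#'
#' The container shared by both regression paths: fixed-length PPG windows
#' paired with SpO2 labels and record identity.
#'
#' @param windows `n x time x 3` array of window values (channel order red,
#'   green, blue).
#' @param label numeric SpO2 labels (%).
#' @param subject_id,hand character vectors of record identity per sample.
#' @param center_time_s reference-reading timestamp each window is centered
#'   on.
#' @param lengths named numeric vector: total recording seconds per subject
#'   (provenance used as normalization weights).
#' @param standardized logical flag; `TRUE` once [standardize()] has been
#'   applied.
#' @return List of class `sample_set`.
#' @export
sample_set <- function(windows, label, subject_id, hand, center_time_s,
                       lengths, standardized = FALSE) {
  n <- if (is.null(windows)) 0L else dim(windows)[1]
  stopifnot(length(label) == n, length(subject_id) == n, length(hand) == n,
            length(center_time_s) == n)
  structure(list(windows = windows, label = as.numeric(label),
                 subject_id = as.character(subject_id),
                 hand = as.character(hand),
                 center_time_s = as.numeric(center_time_s),
                 lengths = lengths, standardized = standardized),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples (%s), %d subjects, window %s\n",
              n_samples(x),
              if (x$standardized) "standardized" else "raw",
              length(unique(x$subject_id)),
              if (n_samples(x)) paste(dim(x$windows)[2], "frames") else "-"))
  invisible(x)
}

#' Number of samples in a sample set
#' @param x a [sample_set()].
#' @export
n_samples <- function(x) {
  if (is.null(x$windows)) 0L else dim(x$windows)[1]
}

#' Concatenate sample sets
#' @param ... [sample_set()] objects.
#' @export
bind_samples <- function(...) {
  sets <- Filter(function(s) n_samples(s) > 0, list(...))
  if (length(sets) == 0) {
    return(sample_set(NULL, numeric(0), character(0), character(0),
                      numeric(0), numeric(0)))
  }
  windows <- do.call(abind3, lapply(sets, `[[`, "windows"))
  lengths <- Reduce(function(a, b) {
    for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0) + b[[nm]]
    a
  }, lapply(sets, `[[`, "lengths"))
  sample_set(windows,
             unlist(lapply(sets, `[[`, "label")),
             unlist(lapply(sets, `[[`, "subject_id")),
             unlist(lapply(sets, `[[`, "hand")),
             unlist(lapply(sets, `[[`, "center_time_s")),
             lengths,
             standardized = sets[[1]]$standardized)
}

# Bind 3-D arrays along the first dimension.
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Subset a sample set
#' @param x a [sample_set()].
#' @param idx integer or logical index over samples.
#' @param drop_lengths recompute provenance lengths to only the subjects
#'   present after subsetting (default TRUE).
#' @export
subset_samples <- function(x, idx, drop_lengths = TRUE) {
  w <- x$windows[idx, , , drop = FALSE]
  lengths <- x$lengths
  sid <- x$subject_id[idx]
  if (drop_lengths) lengths <- lengths[names(lengths) %in% unique(sid)]
  sample_set(w, x$label[idx], sid, x$hand[idx], x$center_time_s[idx],
             lengths, standardized = x$standardized)
}

#' Cut labeled windows from a PPG record
#'
#' Pairs each reference reading with the window of PPG signal centered on
#' its timestamp: a reading at time `t` owns the frames whose timestamps fall
#' in `[t - w/2, t + w/2)` (half-open, left-inclusive), which at 30 fps and
#' `window_seconds = 3` is exactly 90 frames. Candidates whose window crosses
#' a record boundary are dropped, as are candidates labeled below
#' `label_floor` (readings under 70% SpO2 fall outside the validated range
#' of transfer-standard oximeters and are excluded before any statistics).
#'
#' @param ppg a [ppg_record()].
#' @param trace an [oximeter_trace()] on the same clock as `ppg` (frame `i`
#'   at time `(i-1)/fps`).
#' @param window_seconds window length in seconds (default 3).
#' @param label_floor minimum label retained (default 70; strict `<` drops).
#' @return A [sample_set()]; empty (zero samples) when the record is shorter
#'   than one window.
#' @export
make_samples <- function(ppg, trace, window_seconds = 3, label_floor = 70) {
  stopifnot(inherits(ppg, "ppg_record"), inherits(trace, "oximeter_trace"))
  fps <- ppg$fps
  wlen <- round(window_seconds * fps)
  n <- ncol(ppg$values)
  keep_w <- integer(0)
  labels <- numeric(0)
  centers <- numeric(0)
  rows <- list()
  for (k in seq_len(nrow(trace))) {
    t <- trace$time_s[k]
    # frames with (i-1)/fps in [t - w/2, t + w/2)
    i0 <- ceiling((t - window_seconds / 2) * fps - 1e-9) + 1L
    i1 <- i0 + wlen - 1L
    if (i0 < 1L || i1 > n) next
    if (trace$spo2[k] < label_floor) next
    rows[[length(rows) + 1L]] <- t(ppg$values[, i0:i1])
    labels <- c(labels, trace$spo2[k])
    centers <- c(centers, t)
  }
  lengths <- stats::setNames(n / fps, ppg$subject_id)
  if (length(rows) == 0) {
    return(sample_set(NULL, numeric(0), character(0), character(0),
                      numeric(0), lengths))
  }
  windows <- array(0, dim = c(length(rows), wlen, 3))
  for (i in seq_along(rows)) windows[i, , ] <- rows[[i]]
  sample_set(windows, labels,
             rep(ppg$subject_id, length(rows)),
             rep(ppg$hand, length(rows)),
             centers, lengths)
}

#' Cut windows for every record of a cohort
#'
#' Convenience wrapper running [make_samples()] over each hand-record of a
#' [generate_cohort()] result (or an externally loaded cohort in the same
#' layout) and concatenating the results. Per-subject provenance lengths sum
#' over both hands.
#'
#' @param cohort a `cohort` (list of records with `ppg` and `trace`).
#' @inheritParams make_samples
#' @return A [sample_set()].
#' @export
cohort_samples <- function(cohort, window_seconds = 3, label_floor = 70) {
  sets <- lapply(cohort, function(rec) {
    make_samples(rec$ppg, rec$trace, window_seconds, label_floor)
  })
  do.call(bind_samples, sets)
}

#' Normalization statistics of a training partition
#'
#' Channel-wise mean and standard deviation computed as length-weighted
#' combinations of per-subject statistics, the weights proportional to each
#' subject's recording length in seconds. Per-subject moments pool both
#' hands. Weighting by recording length (rather than sample count) keeps a
#' subject with unusually many retained windows from dominating the scale.
#'
#' @param train a raw (unstandardized) [sample_set()] from the training
#'   partition only; validation and test samples must never reach this
#'   function.
#' @return List of class `norm_stats` with `mean`, `sd` (length-3) and
#'   `weights_used`.
#' @export
compute_norm_stats <- function(train) {
  stopifnot(inherits(train, "sample_set"), n_samples(train) > 0)
  if (train$standardized) stop("norm stats must be computed on raw samples")
  subs <- sort(unique(train$subject_id))
  w <- train$lengths[subs]
  if (any(is.na(w)) || any(w <= 0)) stop("positive recording lengths required per subject")
  w <- w / sum(w)
  m <- matrix(0, length(subs), 3)
  m2 <- matrix(0, length(subs), 3)
  for (i in seq_along(subs)) {
    idx <- train$subject_id == subs[i]
    for (c_i in 1:3) {
      v <- as.numeric(train$windows[idx, , c_i])
      m[i, c_i] <- mean(v)
      m2[i, c_i] <- mean(v^2)
    }
  }
  mean_c <- colSums(w * m)
  sd_c <- sqrt(pmax(colSums(w * m2) - mean_c^2, 0))
  if (any(sd_c < 1e-12)) {
    stop("zero-variance channel: ", paste(c("red", "green", "blue")[sd_c < 1e-12],
                                          collapse = ", "))
  }
  structure(list(mean = mean_c, sd = sd_c, weights_used = w),
            class = "norm_stats")
}

#' Standardize a sample set
#'
#' Applies `(value - mean_c) / sd_c` per channel with statistics estimated on
#' the training partition ([compute_norm_stats()]). Labels are untouched.
#' Standardization is not idempotent: applying the same stats twice rescales
#' again; the `standardized` flag guards against it.
#'
#' @param samples a raw [sample_set()].
#' @param stats a `norm_stats` object.
#' @return A standardized [sample_set()].
#' @export
standardize <- function(samples, stats) {
  stopifnot(inherits(samples, "sample_set"), inherits(stats, "norm_stats"))
  if (samples$standardized) stop("sample set is already standardized")
  if (length(stats$mean) != dim(samples$windows)[3]) {
    stop("channel count mismatch between samples and stats")
  }
  w <- samples$windows
  for (c_i in seq_along(stats$mean)) {
    w[, , c_i] <- (w[, , c_i] - stats$mean[c_i]) / stats$sd[c_i]
  }
  out <- samples
  out$windows <- w
  out$standardized <- TRUE
  out
}

#' Invert [standardize()]
#' @inheritParams standardize
#' @export
destandardize <- function(samples, stats) {
  stopifnot(inherits(samples, "sample_set"), inherits(stats, "norm_stats"))
  if (!samples$standardized) stop("sample set is not standardized")
  w <- samples$windows
  for (c_i in seq_along(stats$mean)) {
    w[, , c_i] <- w[, , c_i] * stats$sd[c_i] + stats$mean[c_i]
  }
  out <- samples
  out$windows <- w
  out$standardized <- FALSE
  out
}
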