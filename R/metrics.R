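#' Regression accuracy metrics
#'
#' MAE = mean absolute error; A_rms = root-mean-square error, the accuracy
#' measure used by pulse-oximeter performance standards; R^2 = squared
#' Pearson correlation between predictions and truth (which differs from the
#' regression coefficient of determination when predictions are biased -
#' this is deliberate and documented). A zero-variance truth vector makes
#' the correlation undefined; R^2 is then `NA` with a note.
#'
#' @param pred,truth equal-length numeric vectors (n >= 2).
#' @param subject optional per-sample subject ids; when given, a per-subject
#'   breakdown is included.
#' @return List of class `regression_report`: `mae`, `a_rms`, `r2`, `n`,
#'   optional `per_subject` data frame, optional `note`.
#' @export
regression_metrics <- function(pred, truth, subject = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  err <- pred - truth
  r2 <- NA_real_
  note <- NULL
  if (stats::sd(truth) < 1e-12 || stats::sd(pred) < 1e-12) {
    note <- "R^2 undefined: zero variance in predictions or truth"
  } else {
    r2 <- stats::cor(pred, truth)^2
  }
  per_subject <- NULL
  if (!is.null(subject)) {
    per_subject <- do.call(rbind, lapply(split(seq_along(pred), subject), function(idx) {
      data.frame(subject = subject[idx[1]],
                 mae = mean(abs(err[idx])),
                 a_rms = sqrt(mean(err[idx]^2)),
                 n = length(idx))
    }))
    rownames(per_subject) <- NULL
  }
  structure(list(mae = mean(abs(err)), a_rms = sqrt(mean(err^2)), r2 = r2,
                 n = length(pred), per_subject = per_subject, note = note),
            class = "regression_report")
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and limits of agreement under a normality assumption:
#' `loa = 1.96 * sd(pred - truth)` (half-width). The skewness of the
#' differences is reported alongside so the normality assumption can be
#' checked. The standard deviation uses the usual sample convention
#' (n - 1, so differences (-1, 0, 1) give LOA exactly 1.96);
#' `sd_type = "population"` divides by n instead.
#'
#' @param pred,truth equal-length numeric vectors (n >= 3).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @param subject optional subject ids for a per-subject breakdown.
#' @return List of class `agreement_report`: `mean_diff`, `loa`, `skew`,
#'   `n`, optional `per_subject`.
#' @export
bland_altman <- function(pred, truth, sd_type = c("sample", "population"),
                         subject = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3)
  sd_type <- match.arg(sd_type)
  d <- pred - truth
  sdd <- function(v) {
    if (sd_type == "population") sqrt(mean((v - mean(v))^2)) else stats::sd(v)
  }
  skew <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s < 1e-12) return(0)
    mean((v - mean(v))^3) / s^3
  }
  per_subject <- NULL
  if (!is.null(subject)) {
    per_subject <- do.call(rbind, lapply(split(d, subject), function(v) {
      data.frame(mean_diff = mean(v), loa = 1.96 * sdd(v), n = length(v))
    }))
    per_subject <- cbind(subject = rownames(per_subject), per_subject)
    rownames(per_subject) <- NULL
  }
  structure(list(mean_diff = mean(d), loa = 1.96 * sdd(d), skew = skew(d),
                 n = length(d), sd_type = sd_type, per_subject = per_subject),
            class = "agreement_report")
}

#' Screening classification at a single decision boundary
#'
#' A sample is positive (hypoxemic) when `truth < threshold` and predicted
#' positive when `pred < boundary`; values exactly equal to a cut count as
#' NOT below (strict `<`). Sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). With no positives in truth, sensitivity is
#' undefined and reported `NA` (symmetrically for specificity).
#'
#' @param pred,truth numeric vectors.
#' @param threshold SpO2 level defining true hypoxemia (applied to truth).
#' @param boundary decision boundary applied to predictions.
#' @return List of class `screening_report`: `threshold`, `boundary`,
#'   confusion counts `tp`/`fp`/`tn`/`fn`, `sensitivity`, `specificity`.
#' @export
screen <- function(pred, truth, threshold = 90, boundary = 90) {
  stopifnot(length(pred) == length(truth))
  pos <- truth < threshold
  ppos <- pred < boundary
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  fp <- sum(!pos & ppos); tn <- sum(!pos & !ppos)
  structure(list(threshold = threshold, boundary = boundary,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "screening_report")
}

#' ROC sweep over decision boundaries
#'
#' Sweeps the decision boundary over a grid, computing the fold-averaged
#' false and true positive rates at each boundary (folds without positives
#' or without negatives are excluded from the respective average, with a
#' note). The curve is sorted by FPR with the trivial endpoints (0,0) and
#' (1,1) appended, AUC is the trapezoid integral, and the best operating
#' point is the boundary whose averaged (FPR, TPR) lies closest to the ideal
#' (0, 1) corner in Euclidean distance.
#'
#' @param folds a `loocv_result`, or a list of lists each carrying `pred`
#'   and `truth` (a single pooled set may be passed as a one-element list).
#' @param threshold SpO2 level defining true hypoxemia.
#' @param boundaries decision boundaries to sweep (default 70 to 100 by
#'   0.5).
#' @return List of class `roc_report`: `threshold`, `roc` (data frame with
#'   `boundary`, `fpr`, `tpr`), `auc`, `best_point` (list with `boundary`,
#'   `fpr`, `tpr`, `sensitivity`, `specificity`), `n_folds_used`, `notes`.
#' @export
roc_sweep <- function(folds, threshold = 90, boundaries = seq(70, 100, by = 0.5)) {
  if (inherits(folds, "loocv_result")) folds <- folds$folds
  if (!is.null(folds$pred)) folds <- list(folds)
  stopifnot(length(folds) >= 1)
  notes <- character(0)
  tpr_m <- matrix(NA_real_, length(folds), length(boundaries))
  fpr_m <- matrix(NA_real_, length(folds), length(boundaries))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    pos <- f$truth < threshold
    if (!any(pos)) {
      notes <- c(notes, sprintf("fold %d has no positives; excluded from TPR average", i))
    }
    if (all(pos)) {
      notes <- c(notes, sprintf("fold %d has no negatives; excluded from FPR average", i))
    }
    for (j in seq_along(boundaries)) {
      s <- screen(f$pred, f$truth, threshold, boundaries[j])
      tpr_m[i, j] <- s$sensitivity
      fpr_m[i, j] <- 1 - s$specificity
    }
  }
  tpr <- colMeans(tpr_m, na.rm = TRUE)
  fpr <- colMeans(fpr_m, na.rm = TRUE)
  roc <- data.frame(boundary = boundaries, fpr = fpr, tpr = tpr)
  curve <- rbind(data.frame(boundary = NA, fpr = 0, tpr = 0),
                 roc[order(roc$fpr, roc$tpr), ],
                 data.frame(boundary = NA, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  dist <- sqrt(fpr^2 + (1 - tpr)^2)
  bi <- which.min(dist)
  structure(list(threshold = threshold, roc = roc, auc = auc,
                 best_point = list(boundary = boundaries[bi], fpr = fpr[bi],
                                   tpr = tpr[bi], sensitivity = tpr[bi],
                                   specificity = 1 - fpr[bi]),
                 n_folds_used = length(folds), notes = notes),
            class = "roc_report")
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact-distribution signed-rank test on paired per-subject metric values
#' (for example each subject's MAE under two competing methods). With all
#' differences zero the test is degenerate and reported as such.
#'
#' @param x,y paired numeric vectors (n >= 5 pairs).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic`, `p_value`, `n`, `degenerate`.
#' @export
paired_signed_rank <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  if (all(d == 0)) {
    # no evidence in either direction; flagged so callers cannot mistake
    # this for a real test result
    return(list(statistic = NA_real_, p_value = 1, n = length(d),
                degenerate = TRUE,
                note = "all paired differences are zero"))
  }
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                           alternative = alternative, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Label-floor ablation study
#'
#' For each floor, removes every sample whose ground-truth label falls below
#' it from training, validation and test alike, re-runs the full
#' leave-one-subject-out training, and records the resulting MAE and
#' Bland-Altman agreement. Restricting the label range this way emulates
#' evaluation protocols that never probe deep desaturations; accuracy is
#' expected to improve as the floor rises. Floors leaving any subject with
#' fewer than 10 samples are skipped with a warning.
#'
#' @param samples a raw [sample_set()].
#' @param floors ascending SpO2 floors within \[70, 95\] (default
#'   `c(70, 75, 80, 85)`).
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @return Data frame of class `ablation_report` with one row per completed
#'   floor: `floor`, `n_samples`, `mae`, `mae_sd`, `mean_diff`, `loa`.
#' @export
ablation_study <- function(samples, floors = c(70, 75, 80, 85),
                           spec = model_spec(), config = train_config()) {
  stopifnot(all(diff(floors) > 0), all(floors >= 70), all(floors <= 95))
  rows <- list()
  for (fl in floors) {
    keep <- samples$label >= fl
    sub <- subset_samples(samples, keep, drop_lengths = FALSE)
    counts <- table(sub$subject_id)
    all_subs <- unique(samples$subject_id)
    if (length(counts) < length(all_subs) || any(counts < 10)) {
      warning(sprintf("floor %g leaves a subject with < 10 samples; skipped", fl))
      next
    }
    res <- loocv_cnn(sub, spec, config)
    pred <- unlist(lapply(res$folds, `[[`, "pred"))
    truth <- unlist(lapply(res$folds, `[[`, "truth"))
    ba <- bland_altman(pred, truth)
    rows[[length(rows) + 1L]] <- data.frame(
      floor = fl, n_samples = n_samples(sub), mae = res$mae,
      mae_sd = res$mae_sd, mean_diff = ba$mean_diff, loa = ba$loa)
  }
  structure(do.call(rbind, rows), class = c("ablation_report", "data.frame"))
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> MAE %.3f | A_rms %.3f | R^2 %s | n = %d\n",
              x$mae, x$a_rms,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2), x$n))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> mean diff %.3f | LOA %.3f | skew %.3f (sd: %s)\n",
              x$mean_diff, x$loa, x$skew, x$sd_type))
  invisible(x)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> truth < %g, pred < %g: sens %s, spec %s (TP %d FP %d TN %d FN %d)\n",
              x$threshold, x$boundary,
              if (is.na(x$sensitivity)) "NA" else sprintf("%.2f", x$sensitivity),
              if (is.na(x$specificity)) "NA" else sprintf("%.2f", x$specificity),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> threshold %g: AUC %.3f; best boundary %g (sens %.2f, spec %.2f)\n",
              x$threshold, x$auc, x$best_point$boundary,
              x$best_point$sensitivity, x$best_point$specificity))
  invisible(x)
}
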