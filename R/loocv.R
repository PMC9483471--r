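#' Leave-one-subject-out cross-validation for the CNN
#'
#' One fold per subject. In fold `i`, subject `i` is the test set and is
#' fully excluded from training, validation, and normalization statistics;
#' the validation subject is the next subject in a fixed rotation
#' (`i + 1 mod n`); the remaining subjects form the training set. Both hands
#' of a subject always travel together (the cross-validation unit is the
#' subject), while predictions carry hand identity so results can be
#' reported per hand-record. Headline MAE is the unweighted mean of per-fold
#' MAEs.
#'
#' Each fold also records a mean-predictor baseline: the MAE obtained on the
#' test subject by always predicting the mean of that fold's training
#' labels. A model that fails to beat this is mean-tracking, not measuring.
#'
#' @param samples a raw [sample_set()] for the whole cohort (>= 3 subjects).
#' @param spec a [model_spec()].
#' @param config a [train_config()]; per-fold seeds are derived from
#'   `config$seed`.
#' @return List of class `loocv_result`: `folds` (per-fold list with
#'   `subject`, `pred`, `truth`, `hand`, `center_time_s`, `mae`,
#'   `baseline_mae`, `model`), `mae` (mean of fold MAEs), `mae_sd`,
#'   `baseline_mae`.
#' @export
loocv_cnn <- function(samples, spec = model_spec(), config = train_config()) {
  stopifnot(inherits(samples, "sample_set"))
  if (samples$standardized) stop("loocv requires raw samples")
  subjects <- sort(unique(samples$subject_id))
  if (length(subjects) < 3) {
    stop("leave-one-subject-out cross-validation needs at least 3 subjects")
  }
  n <- length(subjects)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    test_sub <- subjects[i]
    val_sub <- subjects[(i %% n) + 1]
    train_subs <- setdiff(subjects, c(test_sub, val_sub))
    tr <- subset_samples(samples, samples$subject_id %in% train_subs)
    va <- subset_samples(samples, samples$subject_id == val_sub)
    te <- subset_samples(samples, samples$subject_id == test_sub)

    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("fold/", test_sub))
    model <- train_cnn(spec, tr, va, fold_cfg)
    assert_no_leakage(model, tr, va, te)

    pred <- predict_spo2(model, te)
    baseline <- mean(tr$label)
    folds[[i]] <- list(subject = test_sub,
                       val_subject = val_sub,
                       train_subjects = train_subs,
                       pred = pred,
                       truth = te$label,
                       hand = te$hand,
                       center_time_s = te$center_time_s,
                       mae = mean(abs(pred - te$label)),
                       baseline_mae = mean(abs(baseline - te$label)),
                       model = model)
  }
  maes <- vapply(folds, `[[`, numeric(1), "mae")
  structure(list(folds = folds, mae = mean(maes),
                 mae_sd = stats::sd(maes),
                 baseline_mae = mean(vapply(folds, `[[`, numeric(1),
                                            "baseline_mae"))),
            class = "loocv_result")
}

# Hard assertions that a fold never saw its test subject: subject sets are
# disjoint and the normalization weights name only training subjects.
assert_no_leakage <- function(model, train_set, val_set, test_set) {
  te <- unique(test_set$subject_id)
  tr <- unique(train_set$subject_id)
  va <- unique(val_set$subject_id)
  if (length(intersect(te, c(tr, va))) > 0) {
    stop("leakage: test subject present in training or validation partition")
  }
  stat_subs <- names(model$norm_stats$weights_used)
  if (length(intersect(te, stat_subs)) > 0) {
    stop("leakage: test subject contributed to normalization statistics")
  }
  if (length(intersect(va, stat_subs)) > 0) {
    stop("leakage: validation subject contributed to normalization statistics")
  }
  invisible(TRUE)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d folds; MAE %.2f (sd %.2f); mean-predictor baseline %.2f\n",
              length(x$folds), x$mae, x$mae_sd, x$baseline_mae))
  for (f in x$folds) {
    cat(sprintf("  %s: MAE %.2f (baseline %.2f, n = %d)\n",
                f$subject, f$mae, f$baseline_mae, length(f$pred)))
  }
  invisible(x)
}
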