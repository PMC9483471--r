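tiny_exp_config <- function(seed = 5L) {
  experiment_config(
    n_subjects = 3,
    protocol = protocol_config(plateau_hold_s = 10, step_interval_s = 27,
                               total_duration_s = 120,
                               transition_time_constant_s = 5),
    model = tiny_spec(),
    train = tiny_train_config(epochs = 2),
    boundaries = seq(70, 100, by = 2),
    seed = seed)
}

test_that("experiment configs round-trip through YAML", {
  cfg <- tiny_exp_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$protocol$plateau_ranges, cfg$protocol$plateau_ranges)
  expect_equal(back$train$learning_rate, cfg$train$learning_rate)
  expect_equal(back$model$conv_channels, cfg$model$conv_channels)
  expect_equal(back$seed, cfg$seed)
})

test_that("unknown configuration keys are rejected by name", {
  cfg <- tiny_exp_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  y <- yaml::read_yaml(path)
  y$learning_rate_typo <- 1
  yaml::write_yaml(y, path)
  expect_error(read_experiment_config(path), "learning_rate_typo")
  y$learning_rate_typo <- NULL
  y$train$momentumm <- 0.9
  yaml::write_yaml(y, path)
  expect_error(read_experiment_config(path), "momentumm")
})

test_that("cohorts round-trip through the on-disk adapter layout", {
  proto <- protocol_config(plateau_hold_s = 10, step_interval_s = 25,
                           total_duration_s = 110,
                           transition_time_constant_s = 5)
  coh <- generate_cohort(2, proto, camera_model(), seed = 21)
  dir <- withr::local_tempdir()
  export_cohort(coh, dir)
  back <- load_external_dataset(dir)
  expect_setequal(names(back), names(coh))
  for (nm in names(coh)) {
    expect_equal(back[[nm]]$ppg$values, coh[[nm]]$ppg$values,
                 tolerance = 1e-12)
    expect_equal(back[[nm]]$trace$spo2, coh[[nm]]$trace$spo2)
    expect_equal(back[[nm]]$ppg$fps, coh[[nm]]$ppg$fps)
  }
  # loader preserves values exactly enough that downstream windows agree
  s1 <- cohort_samples(coh)
  s2 <- cohort_samples(back)
  expect_equal(s2$windows, s1$windows, tolerance = 1e-12)
  expect_identical(s2$label, s1$label)
})

test_that("a missing reference file aborts the loader with its path", {
  proto <- protocol_config(plateau_hold_s = 10, step_interval_s = 25,
                           total_duration_s = 110,
                           transition_time_constant_s = 5)
  coh <- generate_cohort(1, proto, camera_model(), seed = 3)
  dir <- withr::local_tempdir()
  export_cohort(coh, dir)
  unlink(file.path(dir, "s01_right", "ref.csv"))
  expect_error(load_external_dataset(dir), "ref.csv")
  expect_error(load_external_dataset(file.path(dir, "nope")), "does not exist")
})

test_that("an end-to-end experiment produces reports for both models", {
  cfg <- tiny_exp_config()
  out <- withr::local_tempdir()
  res <- run_experiment(cfg, out)
  expect_true(file.exists(res$paths$reports))
  expect_true(file.exists(res$paths$config))
  ev <- res$evaluation
  for (label in c("cnn", "ror")) {
    expect_true(is.finite(ev[[label]]$mae))
    expect_true(is.finite(ev[[label]]$a_rms))
    expect_true(is.finite(ev[[label]]$loa))
    expect_length(ev[[label]]$screening, 3)
    for (s in ev[[label]]$screening) expect_true(s$auc >= 0 && s$auc <= 1)
  }
})

test_that("evaluation-only changes reuse the cached trained folds", {
  cfg <- tiny_exp_config()
  out <- withr::local_tempdir()
  res1 <- run_experiment(cfg, out)
  cfg2 <- cfg
  cfg2$thresholds <- c(90)          # downstream-only change
  t0 <- Sys.time()
  res2 <- run_experiment(cfg2, out)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(res2$cnn$mae, res1$cnn$mae)
  expect_length(res2$evaluation$cnn$screening, 1)
  expect_lt(elapsed, 30)   # no retraining happened
})
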