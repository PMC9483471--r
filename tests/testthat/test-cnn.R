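test_that("forward pass maps k windows to k scalars", {
  m <- build_model(model_spec(), seed = 1)
  X <- array(rnorm(5 * 90 * 3), c(5, 90, 3))
  pred <- oxicam:::cnn_forward(m$params, X)$pred
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
})

test_that("no-padding convolution arithmetic matches by stage", {
  # 90x3 input, 3x3 kernel, no padding: 88 x 1 spatial output per filter,
  # then 86 and 84 after the two time-only convolutions
  expect_equal(oxicam:::conv_out_lens(model_spec()), c(88, 86, 84))
  expect_error(model_spec(input_len = 5), "minimum")
})

test_that("default architecture parameter count matches the layer-by-layer total", {
  # conv1 3*3*16+16; conv2 3*16*32+32; conv3 3*32*64+64;
  # fc1 (84*64)*64+64; fc2 64+1  ->  352129
  oracle <- (3 * 3 * 16 + 16) + (3 * 16 * 32 + 32) + (3 * 32 * 64 + 64) +
    (84 * 64 * 64 + 64) + (64 + 1)
  expect_equal(n_parameters(build_model(model_spec(), seed = 1)), oracle)
  expect_equal(oracle, 352129)
})

test_that("backpropagation matches finite-difference gradients", {
  spec <- model_spec(conv_channels = c(2, 3, 4), fc_width = 5, input_len = 12)
  m <- build_model(spec, seed = 7)
  set.seed(1)
  X <- array(rnorm(4 * 12 * 3), c(4, 12, 3))
  y <- rnorm(4, 90, 5)
  fw <- oxicam:::cnn_forward(m$params, X, keep_cache = TRUE)
  gr <- oxicam:::cnn_backward(m$params, fw$cache, fw$pred, y)
  loss <- function(p) mean((oxicam:::cnn_forward(p, X)$pred - y)^2)
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (k in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      p2 <- m$params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (loss(p2) - loss(m$params)) / eps
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("learning-rate schedule decays by 0.1 after epoch 80", {
  cfg <- train_config()
  expect_equal(oxicam:::lr_at_epoch(cfg, 80), 1e-5)
  expect_equal(oxicam:::lr_at_epoch(cfg, 81), 1e-6)
})

test_that("network fits a constant-label problem to within 0.5", {
  set.seed(4)
  spec <- model_spec(conv_channels = c(2, 3, 4), fc_width = 5, input_len = 12)
  w_tr <- array(rnorm(40 * 12 * 3), c(40, 12, 3)) + 50
  w_va <- array(rnorm(10 * 12 * 3), c(10, 12, 3)) + 50
  tr <- sample_set(w_tr, rep(85, 40), rep("a", 40), rep("left", 40), 1:40,
                   c(a = 40))
  va <- sample_set(w_va, rep(85, 10), rep("b", 10), rep("left", 10), 1:10,
                   c(b = 10))
  m <- train_cnn(spec, tr, va, train_config(learning_rate = 1e-3,
                                            batch_size = 16, max_epochs = 30,
                                            seed = 2))
  pred <- predict_spo2(m, tr)
  expect_true(all(abs(pred - 85) < 0.5))
})

test_that("training is deterministic given the seed and predictions are stable", {
  samp <- tiny_samples()
  tr <- subset_samples(samp, samp$subject_id == "s01")
  va <- subset_samples(samp, samp$subject_id == "s02")
  cfg <- tiny_train_config(epochs = 2)
  m1 <- train_cnn(tiny_spec(), tr, va, cfg)
  m2 <- train_cnn(tiny_spec(), tr, va, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$train_log, m2$train_log)
  te <- subset_samples(samp, samp$subject_id == "s03")
  p1 <- predict_spo2(m1, te)
  expect_identical(p1, predict_spo2(m1, te))
  # permuting samples permutes predictions identically
  idx <- rev(seq_len(n_samples(te)))
  expect_equal(predict_spo2(m1, subset_samples(te, idx)), p1[idx])
})

test_that("extreme weight decay collapses predictions toward a constant", {
  samp <- tiny_samples()
  tr <- subset_samples(samp, samp$subject_id == "s01")
  va <- subset_samples(samp, samp$subject_id == "s02")
  cfg <- tiny_train_config(epochs = 3)
  cfg$l2_strength <- 1e4
  m <- train_cnn(tiny_spec(), tr, va, cfg)
  pred <- predict_spo2(m, va)
  expect_lt(sd(pred), 0.5)
})

test_that("partition hygiene is enforced", {
  samp <- tiny_samples()
  tr <- subset_samples(samp, samp$subject_id %in% c("s01", "s02"))
  expect_error(train_cnn(tiny_spec(), tr,
                         subset_samples(samp, samp$subject_id == "s02"),
                         tiny_train_config(1)),
               "disjoint")
  m <- train_cnn(tiny_spec(),
                 subset_samples(samp, samp$subject_id == "s01"),
                 subset_samples(samp, samp$subject_id == "s02"),
                 tiny_train_config(1))
  std <- standardize(subset_samples(samp, samp$subject_id == "s03"),
                     m$norm_stats)
  expect_error(predict_spo2(m, std), "raw samples")
})
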