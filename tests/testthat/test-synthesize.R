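test_that("noiseless synthesis is exactly inverted by the ratio-of-ratios path", {
  # forward and inverse share extinction coefficients, so the only error is
  # numerical (discrete sampling of the pulse); contract: within 0.1% SpO2
  for (S in c(72, 85, 97)) {
    ppg <- constant_s_ppg(S)
    R <- window_ror(t(ppg$values), ror_config(), fps = 30)
    expect_lt(abs(spo2_from_ratio(R) - S), 0.1)
  }
})

test_that("zero pulsatility gives a constant trace per channel", {
  opt <- optical_model(noise_sd = 0)
  opt$pulsatility <- 1e-12   # constructor requires > 0; effectively zero
  ppg <- constant_s_ppg(95, seconds = 4, optical = opt)
  for (c_i in 1:3) {
    expect_lt(diff(range(ppg$values[c_i, ])), 1e-6)
  }
})

test_that("callus preset halves AC amplitude and raises DC 1.5x per channel", {
  base <- constant_s_ppg(95, seconds = 8)
  callused <- constant_s_ppg(95, seconds = 8, callus = 0.5, dc_offset = 0.5)
  for (c_i in 1:3) {
    ac_b <- diff(range(base$values[c_i, ]))
    ac_c <- diff(range(callused$values[c_i, ]))
    expect_equal(ac_c / ac_b, 0.5, tolerance = 0.01)
    dc_b <- mean(base$values[c_i, ])
    dc_c <- mean(callused$values[c_i, ])
    # DC term scales 1.5x; the (zero-mean) AC term perturbs the window mean
    # by well under 1%
    expect_equal(dc_c / dc_b, 1.5, tolerance = 0.01)
  }
})

test_that("sensor noise is deterministic given the profile seed", {
  a <- constant_s_ppg(90, seconds = 2, optical = optical_model(noise_sd = 1))
  b <- constant_s_ppg(90, seconds = 2, optical = optical_model(noise_sd = 1))
  expect_identical(a$values, b$values)
})

test_that("noise-free frame rendering followed by extraction is quantization-exact", {
  ppg <- constant_s_ppg(88, seconds = 2)
  cam <- camera_model(spatial_noise_sd = 0, resolution = c(8, 6))
  fr <- synthesize_frames(ppg, cam)
  ex <- extract_ppg(fr)
  expect_equal(ex$values, floor(ppg$values + 0.5), ignore_attr = TRUE)
})

test_that("spatial noise averages out to the per-frame standard error", {
  ppg <- constant_s_ppg(88, seconds = 2)
  cam <- camera_model(spatial_noise_sd = 2)     # full 176x144 sensor
  fr <- synthesize_frames(ppg, cam, seed = 5)
  ex <- extract_ppg(fr)
  err <- abs(ex$values - ppg$values)
  # combined spatial + quantization noise of a pixel mean:
  # sd = sqrt(sigma^2 + 1/12) / sqrt(npix)
  se <- sqrt(cam$spatial_noise_sd^2 + 1 / 12) / sqrt(prod(cam$resolution))
  expect_lt(mean(err), 2 * se)
  expect_lt(max(err), 5 * se)
})

test_that("values beyond the representable range clip to the rail", {
  ppg <- constant_s_ppg(95, seconds = 1)
  ppg$values[3, ] <- 300                       # blue channel beyond 8-bit
  cam <- camera_model(spatial_noise_sd = 0, resolution = c(4, 4))
  fr <- synthesize_frames(ppg, cam)
  blue <- sapply(fr$frames, function(f) f[, , 3])
  expect_true(all(blue == 255))
  rep <- detect_clipping(fr)
  expect_equal(unname(rep$fraction["blue"]), 1.0)
  expect_true(rep$any_flagged)
})

test_that("generated cohorts have two hand-records per subject and are seeded", {
  proto <- protocol_config(plateau_hold_s = 10, step_interval_s = 25,
                           total_duration_s = 110,
                           transition_time_constant_s = 5)
  coh <- generate_cohort(2, proto, camera_model(), seed = 77)
  expect_length(coh, 4)
  expect_setequal(vapply(coh, function(r) r$profile$hand, character(1)),
                  c("left", "right"))
  # both hands share the subject's trajectory
  expect_identical(coh$s01_left$trace, coh$s01_right$trace)
  # but carry independent noise
  expect_false(identical(coh$s01_left$ppg$values, coh$s01_right$ppg$values))
  coh2 <- generate_cohort(2, proto, camera_model(), seed = 77)
  expect_identical(coh, coh2)
})

test_that("cohort label mass below 85% SpO2 exceeds a quarter of samples", {
  samp <- tiny_samples()
  expect_gt(mean(samp$label < 85), 0.25)
})

test_that("reference noise mode perturbs labels at the configured spread", {
  proto <- protocol_config(plateau_hold_s = 10, step_interval_s = 25,
                           total_duration_s = 110,
                           transition_time_constant_s = 5)
  coh <- generate_cohort(1, proto, camera_model(), seed = 5,
                         reference_noise = TRUE, reference_arms = 2)
  clean <- generate_cohort(1, proto, camera_model(), seed = 5)
  d <- coh$s01_left$trace$spo2 - clean$s01_left$trace$spo2
  expect_gt(sd(d), 0.5)
  expect_lt(sd(d), 4)
})
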