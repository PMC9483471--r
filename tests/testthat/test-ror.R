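test_that("beat segmentation finds 2-3 complete beats in 3 s at 70 bpm", {
  ppg <- constant_s_ppg(90, seconds = 4)
  w <- t(ppg$values[, 1:90])
  beats <- segment_beats(w, fps = 30)
  expect_gte(nrow(beats), 2)
  expect_lte(nrow(beats), 3)
  expect_true(all(beats$start < beats$peak & beats$peak <= beats$end))
  expect_true(all(beats$height > 0))
})

test_that("flat signal yields no beats and an unstable window", {
  w <- matrix(100, 90, 3)
  expect_equal(nrow(segment_beats(w, fps = 30)), 0)
  R <- window_ror(w)
  expect_true(is.na(R))
  expect_equal(attr(R, "reason"), "unstable")
})

test_that("a trough-aligned sinusoid is segmented at its mid-cycle extrema", {
  # reflectance dip = inverted signal peak; 1.17 Hz, starting at a trough of
  # the inverted signal means -cos phase
  fps <- 30
  t <- (0:89) / fps
  x <- 100 + 5 * cos(2 * pi * 1.17 * t)   # inverted signal peaks mid-cycle
  w <- matrix(rep(x, 3), ncol = 3)
  beats <- segment_beats(w, fps = 30, config = ror_config(nominal_hr_bpm = 70))
  expect_gte(nrow(beats), 1)
  period <- fps / 1.17
  for (p in beats$peak) {
    # closed form: minima of x (peaks of -x) at odd half-periods
    nearest <- period / 2 + period * round((p - 1 - period / 2) / period)
    expect_lt(abs((p - 1) - nearest), 2)
  }
})

test_that("identical waveforms in both channels give a unit ratio", {
  ppg <- constant_s_ppg(90, seconds = 4)
  w <- t(ppg$values[, 1:90])
  w[, 1] <- w[, 2]
  expect_equal(window_ror(w), 1, tolerance = 1e-9)
})

test_that("constructed AC/DC levels give the analytic ratio", {
  # red AC/DC = 0.02, green AC/DC = 0.04 -> R = 0.5; build cosine pulses as
  # reflectance dips with known trough depth
  fps <- 30
  t <- (0:119) / fps
  pulse <- -cos(2 * pi * (70 / 60) * t)      # dips of depth 1 around 0
  w <- cbind(100 * (1 - 0.01 * pulse),       # AC (peak-to-trough/2)/DC = 0.01
             200 * (1 - 0.02 * pulse),
             150 * (1 - 0.01 * pulse))
  R <- window_ror(w, fps = fps)
  # beat height is measured peak-above-trough-baseline: depth 2*0.01*100 red,
  # 2*0.02*200 green; DC 100 and 200 -> R = 0.02/0.04
  expect_equal(R, 0.5, tolerance = 0.02)
})

test_that("ratio is invariant to rescaling one channel", {
  ppg <- constant_s_ppg(85, seconds = 4)
  w <- t(ppg$values[, 1:90])
  R1 <- window_ror(w)
  w2 <- w
  w2[, 1] <- w2[, 1] * 3.7
  expect_equal(window_ror(w2), R1, tolerance = 1e-9)
})

test_that("the Beer-Lambert inversion hits its closed-form endpoints", {
  cfg <- ror_config()
  expect_equal(spo2_from_ratio(cfg$eps_hb[1] / cfg$eps_hb[2], cfg), 0)
  expect_equal(spo2_from_ratio(cfg$eps_hbo2[1] / cfg$eps_hbo2[2], cfg), 100)
})

test_that("the inversion is monotone in R over the physiologic range", {
  cfg <- ror_config()
  Rs <- seq(spo2_to_ratio(100, cfg), spo2_to_ratio(60, cfg), length.out = 50)
  s <- spo2_from_ratio(Rs, cfg)
  expect_true(all(diff(s) < 0))
})

test_that("end-to-end raw estimates match the generator over the SpO2 grid", {
  for (S in seq(70, 100, 5)) {
    ppg <- constant_s_ppg(S)
    R <- window_ror(t(ppg$values), fps = 30)
    expect_lt(abs(spo2_from_ratio(R) - S), 0.1)
  }
})

test_that("calibration recovers an exact affine relation", {
  set.seed(12)
  n <- 40
  f <- data.frame(subject_id = "a", hand = "left", center_time_s = 1:n,
                  raw_spo2 = runif(n, 70, 100),
                  range_red = runif(n, 1, 3), range_green = runif(n, 20, 40),
                  range_blue = runif(n, 50, 80),
                  upslope_red = NA, upslope_green = NA, upslope_blue = NA,
                  n_beats = 3L, stable = TRUE)
  f$truth <- 5 + 0.9 * f$raw_spo2 + 0.3 * f$range_green - 0.1 * f$range_blue
  cal <- fit_calibration(f)
  expect_lt(max(abs(apply_calibration(cal, f) - f$truth)), 1e-8)
})

test_that("identity truth pins the raw-SpO2 coefficient at one", {
  set.seed(13)
  n <- 50
  f <- data.frame(subject_id = "a", hand = "left", center_time_s = 1:n,
                  raw_spo2 = runif(n, 70, 100),
                  range_red = runif(n), range_green = runif(n),
                  range_blue = runif(n),
                  upslope_red = NA, upslope_green = NA, upslope_blue = NA,
                  n_beats = 3L, stable = TRUE)
  f$truth <- f$raw_spo2
  cal <- fit_calibration(f)
  expect_equal(unname(cal$coefficients["raw_spo2"]), 1, tolerance = 1e-8)
  others <- cal$coefficients[setdiff(names(cal$coefficients), "raw_spo2")]
  expect_lt(max(abs(others)), 1e-7)
})

test_that("rank-deficient calibration designs are reported", {
  set.seed(14)
  n <- 20
  f <- data.frame(subject_id = "a", hand = "left", center_time_s = 1:n,
                  raw_spo2 = runif(n, 70, 100),
                  range_red = 2, range_green = 2, range_blue = 2,
                  upslope_red = NA, upslope_green = NA, upslope_blue = NA,
                  n_beats = 3L, stable = TRUE)
  f$range_green <- f$range_red          # collinear and constant
  f$truth <- f$raw_spo2
  expect_error(fit_calibration(f), "rank-deficient")
})
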