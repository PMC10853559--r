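test_that("distance_signal measures the tip separation and passes constants", {
  clip <- waveform_clip(rep(0.5, 20))
  sig <- distance_signal(clip)
  expect_equal(sig$d, rep(0.5, 20))
  expect_equal(sig$t, (0:19) / 60)

  # 3-4-5 triangle between the two tips
  tri <- fixed_clip(n = 10, thumb_tip = c(4, 0, 0), index_tip = c(4.3, 0.4, 0))
  expect_equal(distance_signal(tri)$d, rep(0.5, 10))

  expect_error(distance_signal(waveform_clip(rep(1, 4))), "at least 5")
  gap <- fixed_clip(n = 10, valid = c(rep(TRUE, 9), FALSE))
  expect_error(distance_signal(gap), "fill_missing")
})

test_that("the 5-frame moving average spreads an impulse to 0.2 at the center", {
  sig <- distance_signal(waveform_clip(c(0, 0, 1, 0, 0)))
  expect_equal(sig$d[3], 0.2)
  # symmetric shrunken edge windows keep ends unbiased for constants
  expect_equal(distance_signal(waveform_clip(rep(2, 7)))$d, rep(2, 7))
})

test_that("peak detection by prominence counts tap cycles", {
  fps <- 60
  t <- seq(0, 10, by = 1 / fps)[-1]
  d <- 0.25 * (1 - cos(2 * pi * 3 * t))       # 3 Hz, peak-to-trough 0.5
  peaks <- detect_peaks(as_distance_signal(d, fps))
  expect_true(abs(nrow(peaks) - 30) <= 1)
  expect_true(all(abs(peaks$height - 0.5) < 1e-6))

  # sub-threshold oscillation: peak-to-trough 0.05 < prominence 0.1
  small <- 0.025 * (1 - cos(2 * pi * 3 * t))
  expect_equal(nrow(detect_peaks(as_distance_signal(small, fps))), 0L)

  ramp <- as_distance_signal(seq(0, 1, length.out = 100), fps)
  expect_equal(nrow(detect_peaks(ramp)), 0L)
})

test_that("prominence uses the higher of the two base saddles", {
  # two peaks: a tall one (1.0) and a shoulder peak (0.6) separated by a
  # saddle at 0.55 -> shoulder prominence is 0.05, tall peak gets full height
  d <- c(0, 1, 0.55, 0.6, 0.3, 0)
  ps <- detect_peaks(as_distance_signal(d, 10), prominence = 0.0)
  expect_equal(ps$height, c(1, 0.6))
  expect_equal(ps$prominence, c(1, 0.05))
  ps2 <- detect_peaks(as_distance_signal(d, 10), prominence = 0.1)
  expect_equal(ps2$height, 1)
})

test_that("STFT recovers a pure tone's frequency and amplitude", {
  fps <- 60
  t <- (0:599) / fps
  sig <- as_distance_signal(0.3 + 0.25 * sin(2 * pi * 3 * t), fps)
  st <- stft_frequency_intensity(sig)
  expect_true(all(abs(st$frequency - 3) <= 0.5))       # within one 0.5 Hz bin
  expect_true(all(abs(st$intensity - 0.25) / 0.25 < 0.1))

  flat <- as_distance_signal(rep(0.4, 600), fps)
  expect_true(all(stft_frequency_intensity(flat)$intensity < 1e-10))

  two <- as_distance_signal(0.05 * sin(2 * pi * 1 * t) + 0.3 * sin(2 * pi * 3 * t), fps)
  expect_true(all(stft_frequency_intensity(two)$frequency == 3))

  expect_error(stft_frequency_intensity(as_distance_signal(rep(1, 30), fps)),
               "window")
})

test_that("FI value is the per-step elementwise product", {
  expect_equal(fi_series(rep(3, 5), rep(0.1, 5)), rep(0.3, 5))
  expect_equal(fi_series(c(2, 4), c(0.2, 0.05)), c(0.4, 0.2))
  expect_equal(fi_series(c(1, 2, 3), c(0, 0, 0)), c(0, 0, 0))
  expect_error(fi_series(1:3, 1:2), "length")
})

test_that("frequency difference is the absolute first difference", {
  expect_equal(frequency_difference(c(3, 3, 1, 3)), c(0, 2, 2))
  expect_equal(frequency_difference(rep(2.5, 6)), rep(0, 5))
  f <- c(1, 1.5, 2.25, 3)
  expect_equal(frequency_difference(f), diff(f))
  expect_error(frequency_difference(3), "at least 2")
})

test_that("summaries take means and medians over steps and peaks", {
  cfg <- tap_sim_config(base_frequency = 3, base_amplitude = 0.25, seed = 4)
  clip <- normalize_clip(simulate_clip(cfg)$clip)
  pars <- tap_parameters(clip)
  s <- summary(pars)
  expect_equal(s$mean[["fi"]], mean(pars$fi))
  expect_equal(s$median[["frequency"]], stats::median(pars$frequency))
  expect_equal(s$median[["peak"]], stats::median(pars$peaks$height))
  expect_false(s$peaks_missing)
  # summaries lie within the range of their series
  expect_gte(s$median[["frequency"]], min(pars$frequency))
  expect_lte(s$mean[["frequency"]], max(pars$frequency))
  expect_gte(s$median[["peak"]], min(pars$peaks$height))

  # explicit arithmetic case
  pars$fi <- c(0.1, 0.2, 0.6)
  pars$frequency <- c(1, 2, 3)
  pars$intensity <- c(0.1, 0.1, 0.2)
  s2 <- summary(pars)
  expect_equal(s2$mean[["fi"]], 0.3)
  expect_equal(s2$median[["fi"]], 0.2)

  # no qualifying peaks -> peak summary flagged missing, rest populated
  pars$peaks <- pars$peaks[0, ]
  s3 <- summary(pars)
  expect_true(s3$peaks_missing)
  expect_true(is.na(s3$median[["peak"]]))
  expect_false(is.na(s3$median[["frequency"]]))
})

test_that("hand parameters are invariant to rigid motion and uniform scale", {
  set.seed(31)
  cfg <- tap_sim_config(base_frequency = 2.5, base_amplitude = 0.2,
                        jitter_sd = 0.005, seed = 9)
  raw <- simulate_clip(cfg)$clip
  base <- tap_parameters(normalize_clip(raw))
  for (i in 1:10) {
    tr <- transform_clip(raw, random_rotation(), scale = stats::runif(1, 0.2, 5),
                         translation = stats::runif(3, -10, 10))
    pars <- tap_parameters(normalize_clip(tr))
    expect_lt(max(abs(pars$frequency - base$frequency)), 1e-6)
    expect_lt(max(abs(pars$intensity - base$intensity) / pmax(base$intensity, 1e-3)), 1e-6)
    expect_lt(max(abs(pars$fi - base$fi) / pmax(base$fi, 1e-3)), 1e-6)
    expect_equal(nrow(pars$peaks), nrow(base$peaks))
    expect_lt(max(abs(pars$peaks$height - base$peaks$height)), 1e-6)
  }
})
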