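test_that("an effect-free simulation round-trips through the analyzer", {
  cfg <- tap_sim_config(duration_s = 10, fps = 60, base_frequency = 3,
                        base_amplitude = 0.25, seed = 17)
  sim <- simulate_clip(cfg)
  expect_equal(n_frames(sim$clip), 600L)
  expect_equal(sim$truth$cycles, 30, tolerance = 0.05)

  pars <- tap_parameters(normalize_clip(sim$clip))
  expect_lte(abs(stats::median(pars$frequency) - 3), 0.5)
  expect_true(abs(nrow(pars$peaks) - 30) <= 1)
  # the cosine distance model swings 0 -> 2A
  expect_lt(abs(stats::median(pars$peaks$height) - 0.5) / 0.5, 0.1)
})

test_that("the clip's thumb chain has unit length before camera scaling", {
  sim <- simulate_clip(tap_sim_config(seed = 1))
  expect_equal(unname(thumb_length(sim$clip)[1]), 1, tolerance = 1e-9)
  sim2 <- simulate_clip(tap_sim_config(seed = 1,
                                       camera = list(angles = c(10, -5, 30),
                                                     scale = 3.7,
                                                     translation = c(1, 2, 3))))
  expect_equal(unname(thumb_length(sim2$clip)[1]), 3.7, tolerance = 1e-9)
})

test_that("frame dropout is exact and feeds quality control", {
  for (rate in c(0, 0.2, 0.3, 0.6)) {
    sim <- simulate_clip(tap_sim_config(missing_rate = rate, seed = 23))
    q <- compute_efr(sim$clip)
    expect_equal(q$efr, rate, tolerance = 1e-9)
  }
})

test_that("freezing silences tapping after its onset", {
  cfg <- tap_sim_config(freeze = TRUE, freeze_onset_s = 5, seed = 6)
  sim <- simulate_clip(cfg)
  pars <- tap_parameters(normalize_clip(sim$clip))
  expect_equal(sum(pars$peaks$time > 5), 0L)
  expect_gt(sum(pars$peaks$time < 4.5), 5)
})

test_that("freeze plus progressive slowing is rejected as inconsistent", {
  expect_error(tap_sim_config(freeze = TRUE, slowing_rate = 0.1), "inconsistent")
})

test_that("hesitations dip both frequency and amplitude in the ground truth", {
  cfg <- tap_sim_config(hesitation = list(rate = 0.3, depth = 0.6, duration_s = 0.5),
                        seed = 41)
  sim <- simulate_clip(cfg)
  expect_gt(length(sim$truth$hesitation_onsets_s), 0)
  o <- sim$truth$hesitation_onsets_s[1]
  inwin <- sim$truth$time >= o & sim$truth$time < o + 0.5
  expect_lt(min(sim$truth$f[inwin]), cfg$base_frequency * 0.6)
  expect_lt(min(sim$truth$A[inwin]), cfg$base_amplitude * 0.6)
})

test_that("cohorts are balanced, unique-subject and reproducible", {
  cohort <- simulate_cohort(n_per_class = 5, seed = 2, duration_s = 6)
  expect_length(cohort, 20L)
  scores <- vapply(cohort, `[[`, integer(1), "item_score")
  expect_equal(as.vector(table(scores)), rep(5L, 4))
  sids <- vapply(cohort, `[[`, character(1), "subject_id")
  expect_equal(anyDuplicated(sids), 0L)
  sides <- vapply(cohort, function(d) d$clip$hand_side, character(1))
  expect_equal(as.vector(table(sides)), c(10L, 10L))

  cohort2 <- simulate_cohort(n_per_class = 5, seed = 2, duration_s = 6)
  expect_identical(lapply(cohort, `[[`, "clip"), lapply(cohort2, `[[`, "clip"))
})

test_that("zero spread recovers each preset frequency within one STFT bin", {
  presets <- severity_presets("left")
  cohort <- simulate_cohort(presets, n_per_class = 3, spread = 0, seed = 5)
  scores <- vapply(cohort, `[[`, integer(1), "item_score")
  for (s in 0:3) {
    meds <- vapply(cohort[scores == s], function(d) {
      stats::median(tap_parameters(normalize_clip(fill_missing(d$clip)))$frequency)
    }, numeric(1))
    expect_lte(abs(stats::median(meds) - presets$frequency[s + 1]), 0.5)
  }
})

test_that("camera pose changes no recovered parameter", {
  base_cfg <- tap_sim_config(base_frequency = 2.2, base_amplitude = 0.2, seed = 77)
  posed_cfg <- base_cfg
  posed_cfg$camera <- list(angles = c(25, -15, 40), scale = 0.4,
                           translation = c(3, -2, 1))
  a <- tap_parameters(normalize_clip(simulate_clip(base_cfg)$clip))
  b <- tap_parameters(normalize_clip(simulate_clip(posed_cfg)$clip))
  expect_equal(a$frequency, b$frequency)
  expect_lt(max(abs(a$intensity - b$intensity) / pmax(a$intensity, 1e-3)), 1e-6)
  expect_lt(max(abs(a$peaks$height - b$peaks$height)), 1e-6)
})

test_that("simulator YAML configs load through the same constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("duration_s: 4", "fps: 30", "base_frequency: 2.5",
               "base_amplitude: 0.2", "seed: 3",
               "hesitation:", "  rate: 0.1", "  depth: 0.5"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "tap_sim_config")
  expect_equal(cfg$fps, 30)
  expect_equal(cfg$hesitation$rate, 0.1)
  expect_equal(cfg$hesitation$duration_s, 0.4)  # default retained
})
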