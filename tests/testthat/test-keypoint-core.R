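test_that("JSON clips round-trip through read_clip and write_clip", {
  clip <- fixed_clip(n = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_clip(clip, path)
  back <- read_clip(path)
  expect_equal(n_frames(back), 10L)
  expect_true(all(back$valid))
  expect_equal(back$coords, clip$coords, tolerance = 1e-12)
  expect_equal(back$fps, clip$fps)
  expect_equal(back$hand_side, clip$hand_side)
})

test_that("frames declared but absent become invalid placeholders", {
  path <- withr::local_tempfile(fileext = ".json")
  write_json_fixture(path, n_frames = 10,
                     frames = lapply(c(0:3, 5, 7, 9), json_frame))
  clip <- read_clip(path)
  expect_equal(n_frames(clip), 10L)
  expect_equal(sum(!clip$valid), 3L)
  expect_false(any(clip$valid[c(5, 7, 9)]))  # 0-based 4, 6, 8
})

test_that("malformed records are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  write_json_fixture(path, n_frames = 5,
                     frames = list(json_frame(0, coords21 = lapply(1:20, function(k) c(k, 0, 0)))))
  expect_error(read_clip(path), "21 landmarks")

  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(hand_side = "left", n_frames = 5, frames = list()),
                       path2, auto_unbox = TRUE)
  expect_error(read_clip(path2), "fps")

  path3 <- withr::local_tempfile(fileext = ".json")
  write_json_fixture(path3, fps = -1, n_frames = 2, frames = list(json_frame(0)))
  expect_error(read_clip(path3), "fps")
})

test_that("CSV schema round-trips and enforces 21 landmarks per frame", {
  clip <- fixed_clip(n = 6, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clip(clip, path)
  back <- read_clip(path)
  expect_equal(n_frames(back), 6L)
  expect_equal(back$valid, clip$valid)
  expect_equal(back$coords[back$valid, , ], clip$coords[clip$valid, , ],
               tolerance = 1e-12)

  # drop one landmark row from a frame -> parse error naming the frame
  lines <- readLines(path)
  drop <- grep("^\"clip\",1,20,", lines)
  expect_length(drop, 1L)
  writeLines(lines[-drop], path)
  expect_error(read_clip(path), "frame 1")
})

test_that("low-confidence frames are demoted to invalid at the floor", {
  path <- withr::local_tempfile(fileext = ".json")
  write_json_fixture(path, n_frames = 3,
                     frames = list(json_frame(0, conf = 0.9),
                                   json_frame(1, conf = 0.3),
                                   json_frame(2)))
  clip <- read_clip(path)
  expect_equal(clip$valid, c(TRUE, FALSE, TRUE))
  clip2 <- read_clip(path, min_confidence = 0.2)
  expect_true(all(clip2$valid))
})

test_that("EFR counts error frames and assigns the quoted confidence tiers", {
  q <- compute_efr(fixed_clip(n = 10, valid = c(rep(TRUE, 7), rep(FALSE, 3))))
  expect_equal(q$efr, 0.3)
  expect_equal(q$n_error_frames, 3L)
  expect_equal(q$confidence, "moderate")

  expect_equal(compute_efr(fixed_clip(n = 10))$efr, 0)
  expect_equal(compute_efr(fixed_clip(n = 10))$confidence, "high")

  # boundary inclusive: EFR exactly 0.5 is low
  q5 <- compute_efr(fixed_clip(n = 10, valid = rep(c(TRUE, FALSE), 5)))
  expect_equal(q5$efr, 0.5)
  expect_equal(q5$confidence, "low")
})

test_that("confidence tiers partition [0, 1]", {
  efrs <- seq(0, 1, by = 0.01)
  tiers <- confidence_tier(efrs)
  expect_true(all(tiers %in% c("high", "moderate", "low")))
  expect_equal(tiers[efrs < 0.16], rep("high", sum(efrs < 0.16)))
  expect_equal(tiers[efrs >= 0.16 & efrs < 0.5],
               rep("moderate", sum(efrs >= 0.16 & efrs < 0.5)))
  expect_equal(tiers[efrs >= 0.5], rep("low", sum(efrs >= 0.5)))
  expect_equal(confidence_tier(c(0.1599, 0.16, 0.4999, 0.5)),
               c("high", "moderate", "moderate", "low"))
})

test_that("thumb length sums the four chain segments and is rigid-motion invariant", {
  m <- matrix(0, 21, 3)
  m[1:5, 1] <- 0:4
  expect_equal(thumb_length(m), 4)

  degenerate <- matrix(0, 21, 3)
  expect_error(thumb_length(degenerate), "degenerate")

  set.seed(71)
  for (i in 1:100) {
    ang <- random_rotation()
    rot <- fingertap:::rotation_matrix_3d(ang)
    shifted <- sweep(m %*% t(rot), 2, stats::runif(3, -5, 5), `+`)
    expect_lt(abs(thumb_length(shifted) - 4), 1e-9)
  }
})

test_that("normalization divides by the median thumb length and is scale invariant", {
  clip <- fixed_clip(n = 8)  # constant thumb length 4
  norm <- normalize_clip(clip)
  expect_equal(attr(norm, "scale_factor"), 4)
  expect_equal(norm$coords, clip$coords / 4, tolerance = 1e-12)

  scaled <- clip
  scaled$coords <- clip$coords * 7.3
  expect_equal(normalize_clip(scaled)$coords, norm$coords, tolerance = 1e-9)

  # idempotent: normalizing a normalized clip changes nothing
  expect_equal(normalize_clip(norm)$coords, norm$coords, tolerance = 1e-9)

  # single valid frame: that frame's thumb length is the factor
  one <- fixed_clip(n = 3, valid = c(FALSE, TRUE, FALSE))
  expect_equal(attr(normalize_clip(one), "scale_factor"), 4)

  none <- fixed_clip(n = 3, valid = rep(FALSE, 3))
  expect_error(normalize_clip(none), "no valid frames")
})

test_that("fill_missing carries the nearest preceding valid frame backward", {
  clip <- fixed_clip(n = 4, valid = c(TRUE, FALSE, FALSE, TRUE))
  clip$coords[1, 9, ] <- c(1, 0, 0)
  clip$coords[4, 9, ] <- c(2, 0, 0)
  filled <- fill_missing(clip)
  expect_true(all(filled$valid))
  expect_equal(filled$coords[2, , ], filled$coords[1, , ])
  expect_equal(filled$coords[3, , ], filled$coords[1, , ])
  expect_equal(filled$coords[4, 9, 1], 2)

  # leading gap copies the first valid frame forward
  lead <- fixed_clip(n = 2, valid = c(FALSE, TRUE))
  lead$coords[2, 9, ] <- c(5, 0, 0)
  expect_equal(fill_missing(lead)$coords[1, , ], fill_missing(lead)$coords[2, , ])

  allv <- fixed_clip(n = 5)
  expect_identical(fill_missing(allv), allv)
  expect_error(fill_missing(fixed_clip(n = 2, valid = c(FALSE, FALSE))),
               "no valid frames")
})

test_that("fill_missing never alters valid frames (property)", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    valid <- stats::runif(n) > 0.4
    if (!any(valid)) valid[sample(n, 1)] <- TRUE
    clip <- fixed_clip(n = n, valid = valid)
    clip$coords[valid, 9, 1] <- stats::rnorm(sum(valid))
    filled <- fill_missing(clip)
    expect_true(all(filled$valid))
    expect_equal(filled$coords[valid, , ], clip$coords[valid, , ])
  }
})

test_that("qc_filter keeps clips with EFR strictly below the cutoff", {
  clips <- list(
    fixed_clip(n = 10, valid = c(rep(TRUE, 9), FALSE)),             # 0.1
    fixed_clip(n = 10, valid = c(rep(TRUE, 7), rep(FALSE, 3))),     # 0.3
    fixed_clip(n = 10, valid = c(rep(TRUE, 4), rep(FALSE, 6)))      # 0.6
  )
  kept <- qc_filter(clips, tefr = 0.5)
  expect_length(kept, 2L)
  expect_identical(kept, clips[1:2])
  expect_length(qc_filter(clips, tefr = 1), 3L)
  expect_length(qc_filter(clips, tefr = 0), 0L)
  expect_length(qc_filter(list(), 0.5), 0L)
})
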