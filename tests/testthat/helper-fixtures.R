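# programmatic fixtures shared across test files

# a clip with every landmark at a fixed position, except the thumb and index
# tips which are placed explicitly per frame
fixed_clip <- function(n = 10, fps = 60, thumb_tip = c(4, 0, 0),
                       index_tip = c(4.3, 0.4, 0), valid = rep(TRUE, n),
                       hand_side = "right") {
  coords <- array(0, c(n, 21, 3))
  # unit-spaced collinear thumb chain along x: total length 4
  for (k in 1:5) coords[, k, 1] <- k - 1
  coords[, 5, ] <- matrix(thumb_tip, n, 3, byrow = TRUE)
  coords[, 9, ] <- matrix(index_tip, n, 3, byrow = TRUE)
  coords[!valid, , ] <- NA_real_
  hand_clip(coords, valid, fps, hand_side)
}

# clip whose (pre-smoothing) thumb-index distance is exactly the waveform d;
# thumb chain is collinear with length 4 and the index tip sits d away from
# the thumb tip along x
waveform_clip <- function(d, fps = 60) {
  n <- length(d)
  coords <- array(0, c(n, 21, 3))
  for (k in 1:5) coords[, k, 1] <- k - 1   # thumb chain, length 4, tip (4,0,0)
  coords[, 9, 1] <- 4 + d                  # index tip along x
  hand_clip(coords, rep(TRUE, n), fps)
}

random_rotation <- function() {
  stats::runif(3, -180, 180)
}

# evaluate an expression right after seeding the RNG (lazy `expr` is forced
# after set.seed runs)
with_seed_draw <- function(seed, expr) {
  set.seed(seed)
  expr
}

# apply a rigid rotation + translation + uniform scaling to a clip's raw
# coordinates (the nuisances a camera introduces)
transform_clip <- function(clip, angles, scale = 1, translation = c(0, 0, 0)) {
  rot <- fingertap:::rotation_matrix_3d(angles)
  n <- dim(clip$coords)[1]
  flat <- matrix(clip$coords, n * 21, 3) %*% t(rot) * scale
  flat <- sweep(flat, 2, translation, `+`)
  out <- clip
  out$coords <- array(flat, dim(clip$coords))
  out
}

# all pairwise inter-landmark distances of one frame
pairwise_dists <- function(clip, frame) {
  as.vector(stats::dist(clip$coords[frame, , ]))
}

# write a minimal keypoint JSON file; frames is a list of records
write_json_fixture <- function(path, fps = 60, hand_side = "right",
                               n_frames, frames) {
  jsonlite::write_json(
    list(fps = fps, hand_side = hand_side, n_frames = n_frames,
         frames = frames),
    path, auto_unbox = TRUE, digits = NA
  )
  path
}

json_frame <- function(i, coords21 = NULL, valid = TRUE, conf = NULL) {
  if (is.null(coords21)) {
    coords21 <- lapply(0:20, function(k) c(k * 0.1, 0, 0))
    # make the thumb chain non-degenerate
    coords21[1:5] <- lapply(0:4, function(k) c(k, 0, 0))
  }
  rec <- list(i = i, valid = valid, lm = coords21)
  if (!is.null(conf)) rec$conf <- conf
  rec
}
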