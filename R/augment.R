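#' Augmentation policy
#'
#' Bundles the two dataset-expansion operators — 3D keypoint rotation and
#' Gaussian-centered random cropping — and the stages at which they apply.
#' The four named model variants of the training protocol correspond to
#' rotation enabled at training only (`t`), training + model-picking (`tp`),
#' training + inference (`ti`) or all three (`tpi`); cropping always runs at
#' every stage because the network consumes fixed-length input.
#'
#' @param stages character subset of `c("training", "model_picking",
#'   "inference")` at which *rotation* augmentation applies.
#' @param rotation_range per-axis half-range of the uniform rotation draw, in
#'   degrees; a single number or a length-3 vector (default 30).
#' @param crop_length crop window in frames (default 300, i.e. 5 s at 60 fps,
#'   the recommended minimum recording).
#' @param crop_sigma_frac s.d. of the Gaussian window-center draw as a
#'   fraction of the croppable span (default 1/6, so +-3 s.d. covers it).
#' @param n_crops,n_rotations number of cropped / rotated views ensembled at
#'   inference (defaults 5 and 1).
#' @param seed integer fixing all augmentation sampling.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(stages = "training", rotation_range = 30,
                           crop_length = 300L, crop_sigma_frac = 1 / 6,
                           n_crops = 5L, n_rotations = 1L, seed = 1L) {
  stages <- match.arg(stages, c("training", "model_picking", "inference"),
                      several.ok = TRUE)
  if (length(rotation_range) == 1L) rotation_range <- rep(rotation_range, 3L)
  stopifnot(length(rotation_range) == 3L, all(is.finite(rotation_range)),
            all(rotation_range >= 0), crop_length >= 1L,
            crop_sigma_frac >= 0, n_crops >= 1L, n_rotations >= 1L)
  structure(
    list(stages = stages, rotation_range = as.numeric(rotation_range),
         crop_length = as.integer(crop_length),
         crop_sigma_frac = crop_sigma_frac,
         n_crops = as.integer(n_crops), n_rotations = as.integer(n_rotations),
         seed = as.integer(seed)),
    class = "augment_policy"
  )
}

# intrinsic rotation matrix, R = Rz(az) %*% Ry(ay) %*% Rx(ax), angles in degrees
rotation_matrix_3d <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Rotate all keypoints of a clip in 3D
#'
#' Applies the composed rotation `Rz(az) Ry(ay) Rx(ax)` to every landmark of
#' every frame, about the clip's mean wrist position. Rotation is an isometry:
#' all pairwise inter-landmark distances — and therefore every distance-based
#' hand parameter — are preserved exactly. Used to emulate videos recorded
#' from different camera angles.
#'
#' @param clip a gap-filled [hand_clip()].
#' @param angles length-3 numeric, degrees about the x, y and z axes.
#' @return The rotated [hand_clip()].
#' @export
rotate_keypoints_3d <- function(clip, angles) {
  stopifnot(inherits(clip, "hand_clip"))
  if (length(angles) != 3L || any(!is.finite(angles))) {
    stop("`angles` must be three finite degrees (ax, ay, az)", call. = FALSE)
  }
  rot <- rotation_matrix_3d(angles)
  center <- colMeans(clip$coords[clip$valid, LM_WRIST, , drop = FALSE][, 1, ])
  n <- n_frames(clip)
  flat <- matrix(clip$coords, n * N_LANDMARKS, 3)
  flat <- sweep(flat, 2, center)
  flat <- flat %*% t(rot)
  flat <- sweep(flat, 2, center, `+`)
  set_coords(clip, array(flat, dim(clip$coords)))
}

#' Draw rotation angles from a policy
#'
#' Per-axis uniform draw on `[-range, +range]` degrees, using R's RNG stream
#' (seed it with [set.seed()] or let the calling stage manage it).
#'
#' @param policy an [augment_policy()].
#' @return length-3 numeric angles in degrees.
#' @export
sample_rotation <- function(policy) {
  r <- policy$rotation_range
  stopifnot(all(is.finite(r)))
  stats::runif(3, -r, r)
}

#' Gaussian-centered random crop of a clip
#'
#' Extracts a contiguous window of exactly `length` frames whose center is
#' drawn from a normal distribution centered on the clip midpoint with s.d.
#' `sigma_frac * (n - length)`, then clipped so the window fits. This favours
#' the middle of the recording, where tapping is usually steady, and trims
#' ragged starts/ends without manual editing.
#'
#' @param clip a [hand_clip()] with at least `length` frames.
#' @param length crop window in frames.
#' @param sigma_frac spread of the center draw as a fraction of the croppable
#'   span; 0 always yields the centered window.
#' @return A [hand_clip()] of exactly `length` frames, metadata preserved.
#' @export
gaussian_random_crop <- function(clip, length = 300L, sigma_frac = 1 / 6) {
  stopifnot(inherits(clip, "hand_clip"))
  n <- n_frames(clip)
  if (n < length) {
    stop(sprintf("clip has %d frames, shorter than the requested %d-frame crop",
                 n, length), call. = FALSE)
  }
  span <- n - length
  mid <- (1 + n) / 2
  center <- if (span == 0L || sigma_frac == 0) mid else
    stats::rnorm(1, mid, sigma_frac * span)
  start <- round(center - (length - 1) / 2)
  start <- min(max(start, 1L), n - length + 1L)
  idx <- seq.int(start, start + length - 1L)
  hand_clip(clip$coords[idx, , , drop = FALSE], clip$valid[idx], clip$fps,
            clip$hand_side, clip$subject_id, clip$visit_id, clip$recorded_at)
}

# right-pad a short clip by repeating its last frame up to `length` frames
pad_clip <- function(clip, length) {
  n <- n_frames(clip)
  if (n >= length) return(clip)
  warning(sprintf("clip has %d frames; right-padding to %d by repeating the last frame",
                  n, length), call. = FALSE)
  extra <- length - n
  coords <- array(0, c(length, N_LANDMARKS, 3))
  coords[seq_len(n), , ] <- clip$coords
  coords[n + seq_len(extra), , ] <- clip$coords[rep(n, extra), , , drop = FALSE]
  hand_clip(coords, c(clip$valid, rep(clip$valid[n], extra)), clip$fps,
            clip$hand_side, clip$subject_id, clip$visit_id, clip$recorded_at)
}

#' Ensemble views of a clip for inference
#'
#' Generates `n_crops x n_rotations` augmented copies: Gaussian random crops,
#' each optionally combined with a random 3D rotation when the policy enables
#' rotation at the inference stage. Averaging predictions over these views
#' acts like an ensemble and stabilizes the estimated score. The view set is
#' deterministic under the policy seed. Clips shorter than the crop length
#' are right-padded by repeating their last frame.
#'
#' @param clip a gap-filled [hand_clip()].
#' @param policy an [augment_policy()].
#' @return list of [hand_clip()] views.
#' @export
inference_views <- function(clip, policy) {
  stopifnot(inherits(policy, "augment_policy"))
  rotate <- "inference" %in% policy$stages
  clip <- pad_clip(clip, policy$crop_length)
  views <- vector("list", policy$n_crops * policy$n_rotations)
  k <- 0L
  with_seed(policy$seed, {
    for (i in seq_len(policy$n_crops)) {
      cropped <- gaussian_random_crop(clip, policy$crop_length, policy$crop_sigma_frac)
      for (j in seq_len(policy$n_rotations)) {
        k <- k + 1L
        views[[k]] <- if (rotate && !(i == 1L && j == 1L)) {
          rotate_keypoints_3d(cropped, sample_rotation(policy))
        } else cropped
      }
    }
  })
  views
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
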