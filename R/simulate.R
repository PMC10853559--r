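#' Configuration of a synthetic finger-tapping clip
#'
#' Describes one simulated recording: base tapping kinematics plus the
#' clinical signatures of bradykinesia visible in the frequency/intensity
#' time courses — hesitations/interruptions (transient dips of both frequency
#' and amplitude), amplitude decrement (progressive loss of excursion),
#' slowing (frequency falling over the task) and freezing (cessation after an
#' onset) — together with measurement nuisances (coordinate jitter, dropped
#' frames, camera pose).
#'
#' @param duration_s clip length in seconds (default 10, a typical recording).
#' @param fps frames per second (default 60).
#' @param base_frequency tapping rate in Hz.
#' @param base_amplitude half the peak-to-trough thumb-index excursion, in
#'   thumb-lengths; the distance signal is `d(t) = A(t) * (1 - cos(phi(t)))`,
#'   so effect-free taps swing from 0 to `2 * base_amplitude`.
#' @param decrement_rate fractional amplitude loss per second
#'   (`A(t) = A0 * exp(-rate * t)`).
#' @param hesitation list with `rate` (events per second), `depth` (fractional
#'   dip of frequency and amplitude, in `[0, 1]`) and `duration_s` of each dip.
#' @param slowing_rate Hz lost per second (frequency floored at 0.3 Hz).
#' @param freeze logical; amplitude ramps to zero after `freeze_onset_s`.
#' @param freeze_onset_s freeze onset (default half the duration).
#' @param jitter_sd s.d. of Gaussian coordinate noise, thumb-lengths.
#' @param missing_rate fraction of frames marked invalid (exact count
#'   `round(rate * n)`, sampled uniformly).
#' @param camera list with `angles` (degrees, length 3), `scale` (> 0) and
#'   `translation` (length 3) applied to all landmarks, emulating camera pose
#'   and distance.
#' @param seed optional integer; when given the simulation is reproducible in
#'   isolation, otherwise it consumes the current RNG stream.
#' @return A `tap_sim_config` list.
#' @export
tap_sim_config <- function(duration_s = 10, fps = 60, base_frequency = 3,
                           base_amplitude = 0.25, decrement_rate = 0,
                           hesitation = list(rate = 0, depth = 0.5, duration_s = 0.4),
                           slowing_rate = 0, freeze = FALSE,
                           freeze_onset_s = duration_s / 2, jitter_sd = 0,
                           missing_rate = 0,
                           camera = list(angles = c(0, 0, 0), scale = 1,
                                         translation = c(0, 0, 0)),
                           seed = NULL) {
  stopifnot(duration_s > 0, fps > 0, base_frequency > 0, base_amplitude >= 0,
            decrement_rate >= 0, slowing_rate >= 0, jitter_sd >= 0,
            missing_rate >= 0, missing_rate < 1, camera$scale > 0)
  hesitation <- utils::modifyList(list(rate = 0, depth = 0.5, duration_s = 0.4),
                                  hesitation)
  stopifnot(hesitation$rate >= 0, hesitation$depth >= 0, hesitation$depth <= 1)
  if (freeze && slowing_rate > 0) {
    stop("inconsistent effects: freezing already silences the task; combining it with progressive slowing is not meaningful",
         call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, fps = fps, base_frequency = base_frequency,
         base_amplitude = base_amplitude, decrement_rate = decrement_rate,
         hesitation = hesitation, slowing_rate = slowing_rate, freeze = freeze,
         freeze_onset_s = freeze_onset_s, jitter_sd = jitter_sd,
         missing_rate = missing_rate, camera = camera, seed = seed),
    class = "tap_sim_config"
  )
}

# canonical 21-landmark right-hand template in thumb-length units: wrist at
# the origin, thumb chain 0-1-2-3-4 rescaled to total length 1, finger chains
# laid out roughly like common hand-pose extractor output. Only the index
# tip (and its two interpolated joints) articulate during tapping.
hand_template <- function() {
  m <- matrix(0, N_LANDMARKS, 3)
  m[2, ] <- c(0.25, 0.12, 0.05)   # thumb CMC
  m[3, ] <- c(0.50, 0.28, 0.10)   # thumb MCP
  m[4, ] <- c(0.68, 0.45, 0.12)   # thumb IP
  m[5, ] <- c(0.80, 0.62, 0.15)   # thumb tip
  chain <- m[LM_THUMB_CHAIN, ]
  len <- sum(sqrt(rowSums(diff(chain)^2)))
  m <- m / len
  m[6, ] <- c(0.30, 0.95, 0)      # index MCP
  m[10, ] <- c(0.10, 1.00, 0)     # middle MCP
  m[14, ] <- c(-0.10, 0.97, 0)    # ring MCP
  m[18, ] <- c(-0.28, 0.88, 0)    # pinky MCP
  for (base in c(10L, 14L, 18L)) {
    dir <- m[base, ] / sqrt(sum(m[base, ]^2))
    for (j in 1:3) m[base + j, ] <- m[base, ] + dir * 0.22 * j
  }
  m
}

#' Simulate one finger-tapping keypoint clip
#'
#' Generates a 21-landmark clip in which the thumb-index distance follows
#' `d(t) = A(t) * (1 - cos(phi(t)))` with `phi'(t) = 2 * pi * f(t)`; the
#' instantaneous frequency `f(t)` and amplitude `A(t)` evolve under the
#' configured clinical effects, after which camera pose, coordinate jitter
#' and frame dropout are applied. The hand template has unit thumb length, so
#' amplitudes are in thumb-lengths before the camera scale.
#'
#' @param cfg a [tap_sim_config()].
#' @param hand_side `"left"` or `"right"` metadata for the clip.
#' @param subject_id,visit_id,recorded_at optional metadata.
#' @return list with `clip` (a [hand_clip()]) and `truth` (per-frame `f`,
#'   `A`, smoothed-state `time`, total `cycles`, hesitation `onsets_s`, and
#'   the config).
#' @export
simulate_clip <- function(cfg, hand_side = "right", subject_id = NULL,
                          visit_id = NULL, recorded_at = NULL) {
  stopifnot(inherits(cfg, "tap_sim_config"))
  run <- function() {
    n <- round(cfg$duration_s * cfg$fps)
    t <- (seq_len(n) - 1L) / cfg$fps
    f <- pmax(0.3, cfg$base_frequency - cfg$slowing_rate * t)
    A <- cfg$base_amplitude * exp(-cfg$decrement_rate * t)
    onsets <- numeric(0)
    if (cfg$hesitation$rate > 0) {
      k <- stats::rpois(1, cfg$hesitation$rate * cfg$duration_s)
      onsets <- sort(stats::runif(k, 0, cfg$duration_s - cfg$hesitation$duration_s))
      for (o in onsets) {
        inwin <- t >= o & t < o + cfg$hesitation$duration_s
        # raised-cosine dip of both frequency and amplitude
        w <- 0.5 - 0.5 * cos(2 * pi * (t[inwin] - o) / cfg$hesitation$duration_s)
        f[inwin] <- f[inwin] * (1 - cfg$hesitation$depth * w)
        A[inwin] <- A[inwin] * (1 - cfg$hesitation$depth * w)
      }
    }
    if (cfg$freeze) {
      # short ramp ending at the onset, so amplitude is exactly 0 from then on
      ramp_s <- 0.2
      fac <- pmin(1, pmax(0, (cfg$freeze_onset_s - t) / ramp_s))
      A <- A * fac
    }
    phi <- 2 * pi * cumsum(f) / cfg$fps
    d <- A * (1 - cos(phi))
    tmpl <- hand_template()
    if (hand_side == "left") tmpl[, 1] <- -tmpl[, 1]
    u <- c(0.2, 1, 0.3)
    u <- u / sqrt(sum(u^2))
    coords <- array(rep(tmpl, each = n), c(n, N_LANDMARKS, 3))
    thumb_tip <- tmpl[LM_THUMB_TIP, ]
    for (ax in 1:3) {
      tip <- thumb_tip[ax] + d * u[ax]
      coords[, LM_INDEX_TIP, ax] <- tip
      # keep the index chain visually continuous between its MCP and tip
      coords[, 7, ax] <- tmpl[6, ax] + 0.4 * (tip - tmpl[6, ax])
      coords[, 8, ax] <- tmpl[6, ax] + 0.7 * (tip - tmpl[6, ax])
    }
    if (cfg$jitter_sd > 0) {
      coords <- coords + stats::rnorm(length(coords), 0, cfg$jitter_sd)
    }
    rot <- rotation_matrix_3d(cfg$camera$angles)
    flat <- matrix(coords, n * N_LANDMARKS, 3) %*% t(rot) * cfg$camera$scale
    flat <- sweep(flat, 2, cfg$camera$translation, `+`)
    coords <- array(flat, c(n, N_LANDMARKS, 3))
    valid <- rep(TRUE, n)
    n_drop <- round(cfg$missing_rate * n)
    if (n_drop > 0) {
      drop <- sample.int(n, n_drop)
      valid[drop] <- FALSE
      coords[drop, , ] <- NA_real_
    }
    clip <- hand_clip(coords, valid, cfg$fps, hand_side, subject_id, visit_id,
                      recorded_at)
    list(clip = clip,
         truth = list(time = t, f = f, A = A, cycles = phi[n] / (2 * pi),
                      hesitation_onsets_s = onsets, config = cfg))
  }
  if (!is.null(cfg$seed)) with_seed(cfg$seed, run()) else run()
}

#' Severity presets anchored on cohort medians
#'
#' Per item score, the median tapping frequency and peak thumb-index
#' excursion observed in a clinical finger-tapping cohort, together with a
#' default mix of clinical effects. The generator's amplitude is half the
#' peak (the cosine distance model swings 0 to 2A). The effect mixes follow
#' the clinical rating anchors for the finger-tapping item: a score of 1 is
#' marked by one or two hesitations over a ~10 s task (rate 0.15/s) with
#' slight decrement, a score of 2 by several hesitations (0.4/s) and mild
#' decrement, and 3+ by frequent hesitations, strong decrement and
#' progressive slowing.
#'
#' @param hand `"left"` or `"right"` reference column.
#' @return data.frame with columns `item_score`, `frequency`, `peak`,
#'   `amplitude`, `decrement_rate`, `hesitation_rate`, `hesitation_depth`,
#'   `slowing_rate`.
#' @export
severity_presets <- function(hand = c("left", "right")) {
  hand <- match.arg(hand)
  ref <- reference_medians(hand)
  data.frame(
    item_score = 0:3,
    frequency = ref$frequency,
    peak = ref$peak,
    amplitude = ref$peak / 2,
    decrement_rate = c(0, 0.015, 0.04, 0.06),
    hesitation_rate = c(0, 0.15, 0.4, 0.6),
    hesitation_depth = c(0, 0.4, 0.5, 0.6),
    slowing_rate = c(0, 0, 0, 0.04)
  )
}

#' Simulate a severity-graded cohort of labeled clips
#'
#' Draws `n_per_class` clips per item score around the preset medians:
#' per-clip frequency and amplitude are lognormal with the preset median and
#' a coefficient of variation `spread` (positivity-preserving), and each clip
#' receives the preset's clinical effect mix. Subjects are unique per clip
#' and hand sides alternate, so patient-level splits are well defined.
#'
#' @param presets a [severity_presets()] data.frame (or compatible).
#' @param n_per_class clips per item score (default 50).
#' @param spread within-class coefficient of variation of frequency and
#'   amplitude (default 0.15).
#' @param seed integer seed fixing the whole cohort.
#' @param duration_s,fps,jitter_sd,missing_rate forwarded to every clip's
#'   [tap_sim_config()].
#' @return list of `labeled_clip` objects: `clip`, `item_score`, `subject_id`.
#' @export
simulate_cohort <- function(presets = severity_presets("left"), n_per_class = 50,
                            spread = 0.15, seed = 1L, duration_s = 10, fps = 60,
                            jitter_sd = 0.01, missing_rate = 0) {
  stopifnot(n_per_class >= 1, spread >= 0)
  sdlog <- sqrt(log(1 + spread^2))
  with_seed(seed, {
    out <- vector("list", nrow(presets) * n_per_class)
    k <- 0L
    for (r in seq_len(nrow(presets))) {
      p <- presets[r, ]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        f <- if (spread > 0) stats::rlnorm(1, log(p$frequency), sdlog) else p$frequency
        a <- if (spread > 0) stats::rlnorm(1, log(p$amplitude), sdlog) else p$amplitude
        cfg <- tap_sim_config(
          duration_s = duration_s, fps = fps, base_frequency = f,
          base_amplitude = a, decrement_rate = p$decrement_rate,
          hesitation = list(rate = p$hesitation_rate, depth = p$hesitation_depth,
                            duration_s = 0.4),
          slowing_rate = p$slowing_rate, jitter_sd = jitter_sd,
          missing_rate = missing_rate
        )
        sid <- sprintf("SYN%04d", k)
        sim <- simulate_clip(cfg, hand_side = if (k %% 2L) "left" else "right",
                             subject_id = sid)
        out[[k]] <- structure(
          list(clip = sim$clip, item_score = p$item_score, subject_id = sid,
               truth = sim$truth),
          class = "labeled_clip"
        )
      }
    }
    sids <- vapply(out, `[[`, character(1), "subject_id")
    stopifnot(!anyDuplicated(sids))
    out
  })
}
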