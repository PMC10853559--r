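#' Smoothed thumb-index distance signal
#'
#' The representative finger-tapping signal: the per-frame Euclidean distance
#' between the thumb tip (landmark 4) and the index-finger tip (landmark 8),
#' passed through a centered 5-frame moving-average filter to suppress
#' extractor jitter. Edge frames use symmetrically shrunken windows, so the
#' filter passes constants unchanged. Distances are in thumb-lengths when the
#' clip has been normalized.
#'
#' @param clip a gap-filled, normalized [hand_clip()] with at least 5 frames.
#' @param smooth_frames odd window width of the moving average (default 5).
#' @return A `distance_signal`: list with `t` (seconds), `d` (distance) and
#'   `fps`.
#' @export
distance_signal <- function(clip, smooth_frames = 5L) {
  stopifnot(inherits(clip, "hand_clip"))
  if (n_frames(clip) < smooth_frames) {
    stop(sprintf("clip has %d frames; at least %d are needed for the %d-frame filter",
                 n_frames(clip), smooth_frames, smooth_frames), call. = FALSE)
  }
  if (!all(clip$valid)) {
    stop("clip contains invalid frames; run fill_missing() first", call. = FALSE)
  }
  stopifnot(smooth_frames >= 1L, smooth_frames %% 2L == 1L)
  tip_diff <- clip$coords[, LM_THUMB_TIP, ] - clip$coords[, LM_INDEX_TIP, ]
  if (is.null(dim(tip_diff))) tip_diff <- matrix(tip_diff, nrow = 1L)
  d <- sqrt(rowSums(tip_diff^2))
  structure(
    list(t = (clip$frame_index - clip$frame_index[1]) / clip$fps,
         d = moving_average(d, smooth_frames), fps = clip$fps),
    class = "distance_signal"
  )
}

# centered moving average; edges shrink symmetrically (half-width limited by
# the distance to the nearer edge) so the filter is unbiased for constants
moving_average <- function(x, width) {
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  hw <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - hw
  hi <- seq_len(n) + hw
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Build a distance signal from raw samples
#'
#' Wraps an already-computed distance trace (e.g. a synthetic waveform) in
#' the container consumed by [detect_peaks()] and
#' [stft_frequency_intensity()]. No smoothing is applied.
#'
#' @param d numeric distance samples (thumb-lengths).
#' @param fps sampling rate in frames per second.
#' @param t optional sample times in seconds (default `(0:(n-1)) / fps`).
#' @return A `distance_signal`.
#' @export
as_distance_signal <- function(d, fps, t = NULL) {
  stopifnot(is.numeric(d), length(d) > 0L, fps > 0)
  if (is.null(t)) t <- (seq_along(d) - 1L) / fps
  stopifnot(length(t) == length(d))
  structure(list(t = t, d = d, fps = fps), class = "distance_signal")
}

#' @export
print.distance_signal <- function(x, ...) {
  cat(sprintf("<distance_signal> %d samples @ %g fps, range [%.3f, %.3f] thumb-lengths\n",
              length(x$d), x$fps, min(x$d), max(x$d)))
  invisible(x)
}

#' Detect tap peaks by topographic prominence
#'
#' Local maxima of the smoothed distance signal whose topographic prominence
#' reaches `prominence`. Prominence is the height of a peak above the higher
#' of the two lowest saddles separating it from higher terrain (or from the
#' signal edge), the same notion used by common signal-processing peak
#' pickers. The default 0.1 corresponds to 10% of the subject's thumb length
#' on a normalized clip.
#'
#' @param sig a [distance_signal()].
#' @param prominence minimum prominence in thumb-lengths (default 0.1).
#' @return data.frame with columns `time` (s), `height` (thumb-lengths),
#'   `index` (1-based sample) and `prominence`; zero rows when nothing
#'   qualifies.
#' @export
detect_peaks <- function(sig, prominence = 0.1) {
  stopifnot(inherits(sig, "distance_signal"), length(sig$d) > 0L,
            is.numeric(prominence), prominence >= 0)
  idx <- local_maxima(sig$d)
  if (!length(idx)) {
    return(data.frame(time = numeric(0), height = numeric(0),
                      index = integer(0), prominence = numeric(0)))
  }
  prom <- vapply(idx, function(p) peak_prominence(sig$d, p), numeric(1))
  keep <- prom >= prominence
  data.frame(time = sig$t[idx[keep]], height = sig$d[idx[keep]],
             index = idx[keep], prominence = prom[keep])
}

# indices of strict local maxima; plateaus contribute their midpoint
local_maxima <- function(d) {
  r <- rle(d)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  j <- j[r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]]
  as.integer((starts[j] + ends[j]) %/% 2L)
}

# height above the higher of the two base saddles; a base saddle is the
# minimum between the peak and the nearest strictly higher sample on that
# side (or the signal edge when no higher sample exists)
peak_prominence <- function(d, p) {
  h <- d[p]
  left <- d[seq_len(p - 1L)]
  higher <- which(left > h)
  lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, p - 1L)])
  right <- d[seq.int(p + 1L, length(d))]
  higher <- which(right > h)
  rmin <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
  h - max(lmin, rmin)
}

#' Per-step elementwise product of frequency and intensity
#'
#' The FI value combines tapping speed and amplitude in one index: the
#' product of the dominant frequency (Hz) and spectral intensity (A.U.) at
#' each analysis step, in A.U./s.
#'
#' @param frequency,intensity equal-length numeric series.
#' @return numeric series of the same length.
#' @export
fi_series <- function(frequency, intensity) {
  if (length(frequency) != length(intensity)) {
    stop(sprintf("frequency (%d) and intensity (%d) series differ in length",
                 length(frequency), length(intensity)), call. = FALSE)
  }
  frequency * intensity
}

#' Absolute step-to-step frequency change
#'
#' `|f[k] - f[k-1]|` for successive analysis steps; transient spikes flag
#' interruptions or hesitations in the tapping rhythm.
#'
#' @param frequency numeric series with at least 2 steps.
#' @return numeric series one element shorter than the input.
#' @export
frequency_difference <- function(frequency) {
  if (length(frequency) < 2L) {
    stop("at least 2 frequency steps are needed for a difference series",
         call. = FALSE)
  }
  abs(diff(frequency))
}
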