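#' Dominant tapping frequency and intensity by short-time Fourier transform
#'
#' Slides a Hann window along the smoothed thumb-index distance signal.
#' In each window the signal is linearly detrended, windowed and Fourier
#' transformed; the dominant bin inside the analysis band gives that step's
#' frequency, and the amplitude-scaled magnitude at the bin gives its
#' intensity. With the `2 / sum(window)` scaling used here, a pure sinusoid
#' of amplitude A (half its peak-to-trough excursion, in thumb-lengths)
#' reports intensity ~ A, so the arbitrary spectral unit stays interpretable
#' as a physical length on a normalized clip.
#'
#' @param sig a [distance_signal()] at least `window_s` long.
#' @param window_s STFT window length in seconds (default 2.0; bin width
#'   `1 / window_s` Hz).
#' @param hop_s hop between successive windows in seconds (default 0.1).
#' @param band two-element Hz range searched for the dominant bin
#'   (default `c(0.5, 8)`, spanning plausible tapping rates).
#' @return list with `step_times` (s, window centers), `frequency` (Hz) and
#'   `intensity` (A.U.).
#' @export
stft_frequency_intensity <- function(sig, window_s = 2.0, hop_s = 0.1,
                                     band = c(0.5, 8)) {
  stopifnot(inherits(sig, "distance_signal"), window_s > 0, hop_s > 0,
            length(band) == 2L, band[1] >= 0, band[2] > band[1])
  fs <- sig$fps
  m <- round(window_s * fs)
  n <- length(sig$d)
  if (n < m) {
    stop(sprintf("signal is %.2f s long; at least %.2f s are needed for the STFT window",
                 n / fs, window_s), call. = FALSE)
  }
  hop <- max(1L, round(hop_s * fs))
  starts <- seq.int(1L, n - m + 1L, by = hop)
  w <- hann_window(m)
  wsum <- sum(w)
  freqs <- (seq_len(m) - 1L) * fs / m
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("analysis band contains no STFT bins", call. = FALSE)
  tt <- (m - 1) / 2
  xt <- seq_len(m)
  frequency <- intensity <- numeric(length(starts))
  for (k in seq_along(starts)) {
    seg <- sig$d[starts[k] + xt - 1L]
    seg <- seg - stats::fitted(stats::lm.fit(cbind(1, xt), seg))
    spec <- Mod(stats::fft(seg * w))[bins]
    j <- which.max(spec)
    frequency[k] <- freqs[bins[j]]
    intensity[k] <- 2 * spec[j] / wsum
  }
  list(step_times = sig$t[starts] + tt / fs,
       frequency = frequency, intensity = intensity)
}

hann_window <- function(m) 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))

#' Compute all hand parameters of one clip
#'
#' End-to-end quantification of a finger-tapping clip: smoothed thumb-index
#' distance, prominence-detected tap peaks, STFT frequency and intensity,
#' their per-step product (the FI value) and the absolute frequency
#' difference series.
#'
#' @param clip a gap-filled, normalized [hand_clip()].
#' @inheritParams stft_frequency_intensity
#' @inheritParams detect_peaks
#' @param smooth_frames moving-average width passed to [distance_signal()].
#' @return A `tap_parameters` object: list with `step_times`, `frequency`,
#'   `intensity`, `fi`, `freq_diff`, `peaks` (data.frame), `signal`
#'   (the [distance_signal()]) and `fps`.
#' @export
tap_parameters <- function(clip, window_s = 2.0, hop_s = 0.1, band = c(0.5, 8),
                           prominence = 0.1, smooth_frames = 5L) {
  sig <- distance_signal(clip, smooth_frames = smooth_frames)
  st <- stft_frequency_intensity(sig, window_s = window_s, hop_s = hop_s,
                                 band = band)
  structure(
    list(step_times = st$step_times,
         frequency = st$frequency,
         intensity = st$intensity,
         fi = fi_series(st$frequency, st$intensity),
         freq_diff = if (length(st$frequency) >= 2L)
           frequency_difference(st$frequency) else numeric(0),
         peaks = detect_peaks(sig, prominence = prominence),
         signal = sig, fps = clip$fps),
    class = "tap_parameters"
  )
}

#' @export
print.tap_parameters <- function(x, ...) {
  cat(sprintf("<tap_parameters> %d STFT steps, %d peaks\n",
              length(x$frequency), nrow(x$peaks)))
  s <- summary(x)
  cat(sprintf("  frequency %.2f Hz, intensity %.3f A.U., FI %.3f A.U./s, peak %s (medians)\n",
              s$median[["frequency"]], s$median[["intensity"]], s$median[["fi"]],
              if (is.na(s$median[["peak"]])) "--" else sprintf("%.3f", s$median[["peak"]])))
  invisible(x)
}

#' Per-clip summary of the four hand parameters
#'
#' Mean and median of frequency, intensity and FI value over STFT steps, and
#' of peak height over detected peaks. When no peak qualifies the peak
#' summary is `NA` and flagged missing; the other parameters stay populated.
#'
#' @param object a [tap_parameters()] object.
#' @param ... unused.
#' @return A `tap_summary`: list with numeric vectors `mean` and `median`
#'   (named `frequency`, `intensity`, `fi`, `peak`), `n_steps`, `n_peaks`
#'   and `peaks_missing`.
#' @export
summary.tap_parameters <- function(object, ...) {
  if (!length(object$frequency)) stop("empty parameter series", call. = FALSE)
  pk <- object$peaks$height
  take <- function(f) c(frequency = f(object$frequency),
                        intensity = f(object$intensity),
                        fi = f(object$fi),
                        peak = if (length(pk)) f(pk) else NA_real_)
  structure(
    list(mean = take(mean), median = take(stats::median),
         n_steps = length(object$frequency), n_peaks = length(pk),
         peaks_missing = !length(pk)),
    class = "tap_summary"
  )
}

#' @export
print.tap_summary <- function(x, ...) {
  df <- data.frame(mean = x$mean, median = x$median)
  cat(sprintf("<tap_summary> over %d steps, %d peaks%s\n", x$n_steps, x$n_peaks,
              if (x$peaks_missing) " (no qualifying peaks)" else ""))
  print(round(df, 4))
  invisible(x)
}

#' @export
as.data.frame.tap_parameters <- function(x, ...) {
  data.frame(step_time = x$step_times, frequency = x$frequency,
             intensity = x$intensity, fi = x$fi,
             freq_diff = c(NA_real_, x$freq_diff))
}

#' Plot the parameter time courses of a clip
#'
#' Three stacked panels: frequency and intensity per STFT step, the smoothed
#' thumb-index distance with detected peaks, and the absolute frequency
#' difference (a hesitation/interruption cue).
#'
#' @param x a [tap_parameters()] object.
#' @param ... unused.
#' @export
plot.tap_parameters <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$step_times, x$frequency, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "frequency (Hz)", main = "STFT parameters")
  graphics::par(new = TRUE)
  graphics::plot(x$step_times, x$intensity, type = "l", col = "firebrick",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("intensity (A.U.)", side = 4, line = 2.5, cex = 0.7)
  graphics::plot(x$signal$t, x$signal$d, type = "l",
                 xlab = "time (s)", ylab = "distance (thumb-lengths)",
                 main = "thumb-index distance")
  if (nrow(x$peaks)) graphics::points(x$peaks$time, x$peaks$height, col = "red", pch = 4)
  if (length(x$freq_diff)) {
    graphics::plot(x$step_times[-1], x$freq_diff, type = "h",
                   xlab = "time (s)", ylab = "|df| (Hz)",
                   main = "absolute frequency difference")
  }
  invisible(x)
}
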