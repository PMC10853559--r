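#' Analyze one finger-tapping clip end to end
#'
#' Runs the full inference pipeline: read (if given a path), quality control,
#' gap repair, thumb-length normalization, hand-parameter extraction and —
#' when a fitted [tap_scorer()] is supplied — item-score estimation. Low
#' keypoint quality downgrades the report's confidence but never aborts the
#' analysis.
#'
#' @param x a [hand_clip()] or a path readable by [read_clip()].
#' @param scorer optional fitted [tap_scorer()].
#' @param keep_series keep the full [tap_parameters()] series in the report
#'   (default `TRUE`; set `FALSE` for compact JSON).
#' @param ... passed to [tap_parameters()] (STFT window, band, prominence...).
#' @return A `clip_report`: `quality` ([compute_efr()] result), `summary`
#'   ([summary.tap_parameters()]), `max_freq_diff` (hesitation cue),
#'   `parameters` (optional series), `score` (optional
#'   [estimate_item_score()] result), `hand_side`, `recorded_at`.
#' @export
analyze_clip <- function(x, scorer = NULL, keep_series = TRUE, ...) {
  clip <- if (inherits(x, "hand_clip")) x else read_clip(x)
  quality <- compute_efr(clip)
  if (!any(clip$valid)) stop("clip has no valid frames; nothing to analyze",
                             call. = FALSE)
  prepared <- normalize_clip(fill_missing(clip))
  pars <- tap_parameters(prepared, ...)
  score <- if (!is.null(scorer)) estimate_item_score(clip, scorer) else NULL
  structure(
    list(quality = quality, summary = summary(pars),
         max_freq_diff = if (length(pars$freq_diff)) max(pars$freq_diff) else NA_real_,
         parameters = if (keep_series) pars else NULL, score = score,
         hand_side = clip$hand_side, subject_id = clip$subject_id,
         recorded_at = clip$recorded_at),
    class = "clip_report"
  )
}

#' @export
print.clip_report <- function(x, ...) {
  cat(sprintf("<clip_report> %s hand%s\n", x$hand_side,
              if (!is.null(x$recorded_at)) paste0(" @ ", x$recorded_at) else ""))
  cat(sprintf("  quality: EFR %.3f -> confidence %s\n", x$quality$efr,
              x$quality$confidence))
  if (!is.null(x$score)) {
    cat(sprintf("  estimated item score: %s\n", x$score$label))
  }
  s <- x$summary
  cat(sprintf("  medians: frequency %.2f Hz, intensity %.3f A.U., FI %.3f A.U./s, peak %s\n",
              s$median[["frequency"]], s$median[["intensity"]], s$median[["fi"]],
              if (is.na(s$median[["peak"]])) "--" else sprintf("%.3f", s$median[["peak"]])))
  cat(sprintf("  max |frequency difference|: %s Hz\n",
              if (is.na(x$max_freq_diff)) "--" else sprintf("%.2f", x$max_freq_diff)))
  invisible(x)
}

#' Map a hand parameter onto the 80-20 severity scale
#'
#' Piecewise-linear transform anchored on the cohort reference medians: the
#' score-0 median maps to 80, score-1 to 60, score-2 to 40 and score-3+ to
#' 20, with linear extrapolation beyond the end anchors clipped to
#' `[0, 100]`. Higher is better on the scaled axis regardless of the raw
#' parameter's direction, which makes parameters comparable on one radar
#' plot.
#'
#' @param value raw parameter value(s).
#' @param reference_medians length-4 numeric, the per-score medians for this
#'   parameter, strictly monotone across scores 0, 1, 2, 3+.
#' @return scaled value(s) in `[0, 100]`.
#' @export
radar_scale <- function(value, reference_medians) {
  r <- as.numeric(reference_medians)
  stopifnot(length(r) == 4L, all(is.finite(r)))
  dr <- diff(r)
  if (!(all(dr < 0) || all(dr > 0))) {
    stop("reference medians must be strictly monotone across scores",
         call. = FALSE)
  }
  anchors <- c(80, 60, 40, 20)
  if (dr[1] > 0) { r <- rev(r); anchors <- rev(anchors) }
  # r now strictly decreasing; piecewise-linear with end extrapolation
  vapply(value, function(v) {
    if (v >= r[1]) {
      s <- anchors[1] + (anchors[2] - anchors[1]) * (r[1] - v) / (r[1] - r[2])
    } else if (v <= r[4]) {
      s <- anchors[4] + (anchors[4] - anchors[3]) * (r[4] - v) / (r[3] - r[4])
    } else {
      i <- max(which(r >= v))  # segment [r[i], r[i+1]]
      s <- anchors[i] + (anchors[i + 1] - anchors[i]) * (r[i] - v) / (r[i] - r[i + 1])
    }
    min(100, max(0, s))
  }, numeric(1))
}

#' Left/right radar comparison of two scored reports
#'
#' Builds the 80-20 scaled profile of each hand — the four hand-parameter
#' medians plus the estimated item score (score 0 maps to 80, 3+ to 20) —
#' and flags asymmetry when the two estimated scores differ. Marked
#' left/right asymmetry is typical of Parkinson's disease, whereas atypical
#' parkinsonism tends to impair both sides alike.
#'
#' @param left,right [analyze_clip()] reports of the two hands, both scored.
#' @param reference optional reference-median table ([reference_medians()]
#'   format with both hands).
#' @return A `radar_profile`: `profiles` (2 x 5 matrix of scaled values),
#'   `asymmetry` flag and the raw item scores.
#' @export
compare_hands <- function(left, right, reference = reference_medians("both")) {
  stopifnot(inherits(left, "clip_report"), inherits(right, "clip_report"))
  if (is.null(left$score) || is.null(right$score)) {
    stop("both reports must carry an estimated item score; run analyze_clip() with a scorer",
         call. = FALSE)
  }
  if (left$hand_side == right$hand_side) {
    stop("`left` and `right` must come from opposite hands", call. = FALSE)
  }
  if (left$hand_side != "left") { tmp <- left; left <- right; right <- tmp }
  one <- function(rep_) {
    ref <- reference[reference$hand == rep_$hand_side, ]
    ref <- ref[order(ref$item_score), ]
    med <- rep_$summary$median
    c(frequency = radar_scale(med[["frequency"]], ref$frequency),
      intensity = radar_scale(med[["intensity"]], ref$intensity),
      fi = radar_scale(med[["fi"]], ref$fi),
      peak = if (is.na(med[["peak"]])) 0 else radar_scale(med[["peak"]], ref$peak),
      score = 80 - 20 * rep_$score$item_score)
  }
  profiles <- rbind(left = one(left), right = one(right))
  structure(
    list(profiles = profiles,
         asymmetry = left$score$item_score != right$score$item_score,
         scores = c(left = left$score$item_score, right = right$score$item_score)),
    class = "radar_profile"
  )
}

#' @export
print.radar_profile <- function(x, ...) {
  cat(sprintf("<radar_profile> item scores left %d / right %d%s\n",
              x$scores[["left"]], x$scores[["right"]],
              if (x$asymmetry) " (asymmetric)" else ""))
  print(round(x$profiles, 1))
  invisible(x)
}

#' Radar plot of a left/right comparison
#'
#' @param x a [compare_hands()] profile.
#' @param ... unused.
#' @export
plot.radar_profile <- function(x, ...) {
  axes <- colnames(x$profiles)
  k <- length(axes)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  graphics::plot(NA, xlim = c(-120, 120), ylim = c(-120, 120), axes = FALSE,
                 xlab = "", ylab = "", asp = 1, main = "left vs right hand (80-20 scale)")
  for (rr in c(20, 40, 60, 80, 100)) {
    graphics::polygon(rr * cos(ang), rr * sin(ang), border = "grey85")
  }
  graphics::text(112 * cos(ang), 112 * sin(ang), axes, cex = 0.8)
  cols <- c(left = "steelblue", right = "firebrick")
  for (side in rownames(x$profiles)) {
    v <- x$profiles[side, ]
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[[side]],
                      col = grDevices::adjustcolor(cols[[side]], 0.2))
  }
  graphics::legend("topright", legend = rownames(x$profiles),
                   col = cols[rownames(x$profiles)], lwd = 2, bty = "n")
  invisible(x)
}

#' Longitudinal series of one hand parameter
#'
#' Orders a set of clip reports by their recording time and extracts the
#' summary value of one parameter, for tracking progression across visits.
#'
#' @param reports list of [analyze_clip()] reports with `recorded_at` set.
#' @param parameter one of `"frequency"`, `"intensity"`, `"fi"`, `"peak"`.
#' @param stat `"median"` (default) or `"mean"`.
#' @return data.frame with `recorded_at` and `value`, chronologically sorted.
#' @export
track_history <- function(reports, parameter = "frequency", stat = "median") {
  parameter <- match.arg(parameter, c("frequency", "intensity", "fi", "peak"))
  stat <- match.arg(stat, c("median", "mean"))
  has_time <- vapply(reports, function(r) !is.null(r$recorded_at), logical(1))
  reports <- reports[has_time]
  if (!length(reports)) {
    stop("at least one report with `recorded_at` is needed", call. = FALSE)
  }
  ts <- vapply(reports, function(r) as.character(r$recorded_at), character(1))
  vals <- vapply(reports, function(r) r$summary[[stat]][[parameter]], numeric(1))
  ord <- order(ts)
  data.frame(recorded_at = ts[ord], value = vals[ord])
}

#' Serialize a clip report to JSON
#'
#' @param report a [analyze_clip()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    hand_side = report$hand_side,
    recorded_at = if (!is.null(report$recorded_at)) as.character(report$recorded_at),
    quality = report$quality[c("n_frames", "n_error_frames", "efr", "confidence")],
    summary = list(mean = as.list(report$summary$mean),
                   median = as.list(report$summary$median)),
    max_freq_diff = report$max_freq_diff
  )
  if (!is.null(report$score)) {
    obj$score <- list(item_score = report$score$label,
                      boundary_probs = as.list(report$score$boundary_probs),
                      confidence = report$score$confidence)
  }
  if (!is.null(report$parameters)) {
    obj$series <- as.data.frame(report$parameters)
    obj$peaks <- report$parameters$peaks
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
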