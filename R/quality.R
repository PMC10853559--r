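#' Error-frame ratio and confidence tier of a clip
#'
#' The error-frame ratio (EFR) is the proportion of frames in which hand
#' keypoints were not successfully extracted. It maps to a confidence tier:
#' high (EFR < 0.16), moderate (0.16 <= EFR < 0.5), low (EFR >= 0.5).
#'
#' @param clip a [hand_clip()].
#' @return A `quality_report`: list with `n_frames`, `n_error_frames`, `efr`
#'   and `confidence` (`"high"`, `"moderate"` or `"low"`).
#' @export
compute_efr <- function(clip) {
  stopifnot(inherits(clip, "hand_clip"))
  n <- n_frames(clip)
  nerr <- sum(!clip$valid)
  efr <- nerr / n
  structure(
    list(n_frames = n, n_error_frames = nerr, efr = efr,
         confidence = confidence_tier(efr)),
    class = "quality_report"
  )
}

#' Confidence tier for an error-frame ratio
#'
#' @param efr error-frame ratio in `[0, 1]`.
#' @return `"high"` if `efr < 0.16`, `"moderate"` if `0.16 <= efr < 0.5`,
#'   `"low"` if `efr >= 0.5`. Vectorized.
#' @export
confidence_tier <- function(efr) {
  stopifnot(all(is.finite(efr)), all(efr >= 0 & efr <= 1))
  ifelse(efr < 0.16, "high", ifelse(efr < 0.5, "moderate", "low"))
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d/%d error frames, EFR %.3f, confidence %s\n",
              x$n_error_frames, x$n_frames, x$efr, x$confidence))
  invisible(x)
}

#' Filter clips by error-frame ratio
#'
#' Retains the clips whose EFR is strictly below the cutoff `tefr`
#' (threshold on the error-frame ratio). With `tefr = 0.5` this drops exactly
#' the low-confidence tier, whose definition is EFR >= 0.5.
#'
#' @param clips list of [hand_clip()] objects.
#' @param tefr cutoff in `[0, 1]` (the study used 0.3 or 0.5).
#' @return The retained sublist, input order preserved.
#' @export
qc_filter <- function(clips, tefr = 0.5) {
  stopifnot(is.numeric(tefr), length(tefr) == 1L, tefr >= 0, tefr <= 1)
  keep <- vapply(clips, function(cl) compute_efr(cl)$efr < tefr, logical(1))
  clips[keep]
}

#' Repair invalid frames by carrying valid keypoints backward in time
#'
#' Each invalid frame takes the landmarks of the nearest preceding valid
#' frame ("tracking back"); invalid frames before the first valid frame copy
#' the first valid frame forward. Valid frames are never altered, and the
#' output contains no invalid frames.
#'
#' @param clip a [hand_clip()] with at least one valid frame.
#' @return A [hand_clip()] with `valid` all `TRUE`.
#' @export
fill_missing <- function(clip) {
  stopifnot(inherits(clip, "hand_clip"))
  if (!any(clip$valid)) {
    stop("cannot fill a clip with no valid frames", call. = FALSE)
  }
  if (all(clip$valid)) return(clip)
  n <- n_frames(clip)
  # source index per frame: last valid frame at or before it, else first valid
  vi <- which(clip$valid)
  src <- cummax(ifelse(clip$valid, seq_len(n), 0L))
  src[src == 0L] <- vi[1]
  coords <- clip$coords[src, , , drop = FALSE]
  set_coords(clip, coords, valid = rep(TRUE, n))
}
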