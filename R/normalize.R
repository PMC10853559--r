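#' Thumb length of each frame
#'
#' The thumb length is the sum of the Euclidean distances along the
#' wrist-to-thumb-tip chain (landmarks 0-1, 1-2, 2-3, 3-4): four segments
#' linking the palm keypoint to the four thumb keypoints. It is the clip's
#' intrinsic length unit, invariant to rigid motion of the hand and
#' proportional to any uniform rescaling of the coordinates.
#'
#' @param x a [hand_clip()] (returns one length per frame, `NA` for invalid
#'   frames) or a single-frame `21 x 3` landmark matrix.
#' @return numeric vector of lengths in extractor units.
#' @export
thumb_length <- function(x) {
  if (inherits(x, "hand_clip")) {
    chain <- x$coords[, LM_THUMB_CHAIN, , drop = FALSE]
    seg <- chain[, -1L, , drop = FALSE] - chain[, -5L, , drop = FALSE]
    len <- rowSums(sqrt(apply(seg^2, c(1, 2), sum)))
    len[!x$valid] <- NA_real_
    if (any(!is.na(len) & len <= 0)) {
      stop("degenerate hand geometry: zero thumb length in a valid frame",
           call. = FALSE)
    }
    return(len)
  }
  if (!is.matrix(x) || nrow(x) != N_LANDMARKS || ncol(x) != 3L) {
    stop("`x` must be a hand_clip or a 21 x 3 landmark matrix", call. = FALSE)
  }
  if (any(!is.finite(x[LM_THUMB_CHAIN, ]))) {
    stop("cannot measure thumb length of an invalid frame", call. = FALSE)
  }
  seg <- diff(x[LM_THUMB_CHAIN, , drop = FALSE])
  len <- sum(sqrt(rowSums(seg^2)))
  if (len <= 0) {
    stop("degenerate hand geometry: zero thumb length", call. = FALSE)
  }
  len
}

#' Scale factor used for thumb-length normalization
#'
#' The median per-frame thumb length over valid frames. The median resists
#' extractor jitter and occasional foreshortened frames.
#'
#' @param clip a [hand_clip()] with at least one valid frame.
#' @return single positive number in extractor units.
#' @export
clip_scale_factor <- function(clip) {
  len <- thumb_length(clip)
  len <- len[!is.na(len)]
  if (!length(len)) {
    stop("cannot normalize a clip with no valid frames", call. = FALSE)
  }
  stats::median(len)
}

#' Normalize a clip to thumb-length units
#'
#' Divides every coordinate by the clip's scale factor (median per-frame
#' thumb length over valid frames), expressing all geometry in units of the
#' subject's thumb. This removes camera distance and hand size: a clip whose
#' raw coordinates are uniformly rescaled normalizes to the same result.
#'
#' @param clip a [hand_clip()] with at least one valid frame.
#' @param factor optional explicit scale factor; defaults to
#'   [clip_scale_factor()].
#' @return A [hand_clip()] in thumb-length units, with the factor stored in
#'   `attr(, "scale_factor")`.
#' @export
normalize_clip <- function(clip, factor = NULL) {
  stopifnot(inherits(clip, "hand_clip"))
  if (is.null(factor)) factor <- clip_scale_factor(clip)
  stopifnot(is.numeric(factor), length(factor) == 1L, is.finite(factor), factor > 0)
  out <- set_coords(clip, clip$coords / factor)
  attr(out, "scale_factor") <- factor
  out
}
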