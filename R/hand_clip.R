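# Landmark layout follows the common 21-landmark hand convention
# (0 = wrist, 1-4 = thumb chain ending at the tip, 8 = index-finger tip).
# R storage is 1-based: landmark k of the convention sits at index k + 1.
LM_WRIST <- 1L
LM_THUMB_CHAIN <- 1:5
LM_THUMB_TIP <- 5L
LM_INDEX_TIP <- 9L
N_LANDMARKS <- 21L

#' Construct a hand-keypoint clip
#'
#' A `hand_clip` holds one finger-tapping recording: an ordered sequence of
#' frames, each carrying 21 three-dimensional hand landmarks and a validity
#' flag. Invalid frames (keypoint extraction failed, or extractor confidence
#' below the acceptance floor) carry `NA` coordinates.
#'
#' @param coords numeric array `n_frames x 21 x 3` of landmark coordinates in
#'   extractor units. Rows belonging to invalid frames may be `NA`.
#' @param valid logical vector of length `n_frames`; `FALSE` marks frames
#'   whose keypoints were not successfully extracted.
#' @param fps frames per second of the source video (> 0).
#' @param hand_side `"left"` or `"right"`.
#' @param subject_id,visit_id optional identifiers used for patient-level
#'   dataset splitting and longitudinal tracking.
#' @param recorded_at optional timestamp (anything orderable; `POSIXct` or
#'   ISO-8601 string).
#' @param frame_index optional integer vector of 0-based source frame indices,
#'   strictly increasing; defaults to `0:(n_frames - 1)`.
#'
#' @return An object of class `hand_clip`.
#' @export
hand_clip <- function(coords, valid, fps, hand_side = c("left", "right"),
                      subject_id = NULL, visit_id = NULL, recorded_at = NULL,
                      frame_index = NULL) {
  hand_side <- match.arg(hand_side)
  if (length(dim(coords)) != 3L || dim(coords)[2] != N_LANDMARKS ||
      dim(coords)[3] != 3L) {
    stop("`coords` must be an n_frames x 21 x 3 array", call. = FALSE)
  }
  n <- dim(coords)[1]
  if (n == 0L) stop("a hand_clip must contain at least one frame", call. = FALSE)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("`valid` must have one flag per frame", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || any(diff(frame_index) <= 0L) || frame_index[1] < 0L) {
    stop("`frame_index` must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(valid)) {
    bad <- which(valid & apply(!is.finite(coords), 1, any))
    if (length(bad)) {
      stop("valid frame(s) ", paste(frame_index[bad[seq_len(min(5, length(bad)))]],
                                    collapse = ", "),
           " contain non-finite landmark coordinates", call. = FALSE)
    }
  }
  structure(
    list(coords = coords, valid = valid, fps = as.numeric(fps),
         hand_side = hand_side, subject_id = subject_id, visit_id = visit_id,
         recorded_at = recorded_at, frame_index = frame_index),
    class = "hand_clip"
  )
}

#' @export
print.hand_clip <- function(x, ...) {
  cat(sprintf("<hand_clip> %d frames @ %g fps, %s hand (%.1f s)\n",
              n_frames(x), x$fps, x$hand_side, n_frames(x) / x$fps))
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  nbad <- sum(!x$valid)
  cat(sprintf("  invalid frames: %d (%.1f%%)\n", nbad, 100 * nbad / n_frames(x)))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip a [hand_clip()].
#' @return integer frame count.
#' @export
n_frames <- function(clip) {
  stopifnot(inherits(clip, "hand_clip"))
  dim(clip$coords)[1]
}

#' Duration of a clip in seconds
#' @inheritParams n_frames
#' @return numeric seconds.
#' @export
clip_duration <- function(clip) n_frames(clip) / clip$fps

# replace the coordinate array, keeping metadata
set_coords <- function(clip, coords, valid = clip$valid,
                       frame_index = clip$frame_index) {
  hand_clip(coords, valid, clip$fps, clip$hand_side, clip$subject_id,
            clip$visit_id, clip$recorded_at, frame_index)
}

#' Read a hand-keypoint clip from disk
#'
#' Two schemas are supported. JSON:
#' `{"fps": .., "hand_side": "left|right", "n_frames": .., "frames":`
#' `[{"i": .., "valid": .., "lm": [[x,y,z] x 21], "conf": ..}, ...]}`.
#' Long CSV: columns `clip_id, frame, landmark, x, y, z, valid` (0-based
#' `frame` and `landmark`) with metadata given as leading comment lines
#' `# fps: 60`, `# hand_side: left`, `# n_frames: 600`.
#'
#' Frames declared by `n_frames` but absent from the file are materialized as
#' invalid placeholders, so quality control sees extraction dropouts. Frames
#' whose extractor confidence (`conf`, optional) falls below `min_confidence`
#' are demoted to invalid: low-confidence keypoints are discarded rather than
#' trusted.
#'
#' @param path file to read.
#' @param schema `"auto"` (by file extension), `"json"` or `"csv"`.
#' @param min_confidence confidence floor in `[0, 1]` below which a frame is
#'   treated as invalid (default 0.5). Only consulted when the file carries a
#'   per-frame confidence.
#' @return A [hand_clip()].
#' @export
read_clip <- function(path, schema = c("auto", "json", "csv"),
                      min_confidence = 0.5) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (schema == "auto") {
    schema <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (schema == "json") read_clip_json(path, min_confidence)
  else read_clip_csv(path, min_confidence)
}

read_clip_json <- function(path, min_confidence) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("fps", "hand_side", "n_frames", "frames")) {
    if (is.null(obj[[f]])) {
      stop(sprintf("keypoint JSON '%s' lacks required field '%s'", path, f),
           call. = FALSE)
    }
  }
  fps <- as.numeric(obj$fps)
  if (!is.finite(fps) || fps <= 0) {
    stop(sprintf("keypoint JSON '%s': fps must be > 0", path), call. = FALSE)
  }
  n <- as.integer(obj$n_frames)
  coords <- array(NA_real_, c(n, N_LANDMARKS, 3))
  valid <- rep(FALSE, n)
  for (rec in obj$frames) {
    i <- as.integer(rec$i)
    if (is.na(i) || i < 0L || i >= n) {
      stop(sprintf("frame record with index %s outside declared range [0, %d)",
                   deparse(rec$i), n), call. = FALSE)
    }
    v <- isTRUE(as.logical(rec$valid))
    if (v && !is.null(rec$conf) && as.numeric(rec$conf) < min_confidence) v <- FALSE
    if (v) {
      lm <- rec$lm
      if (length(lm) != N_LANDMARKS) {
        stop(sprintf("frame %d: expected 21 landmarks, found %d", i, length(lm)),
             call. = FALSE)
      }
      m <- do.call(rbind, lapply(lm, function(p) as.numeric(p)[1:3]))
      if (any(!is.finite(m))) {
        stop(sprintf("frame %d: non-finite landmark coordinates", i), call. = FALSE)
      }
      coords[i + 1L, , ] <- m
      valid[i + 1L] <- TRUE
    }
  }
  hand_clip(coords, valid, fps, obj$hand_side,
            subject_id = obj$subject_id, visit_id = obj$visit_id,
            recorded_at = obj$recorded_at)
}

read_clip_csv <- function(path, min_confidence) {
  header <- readLines(path, n = 50L)
  header <- header[startsWith(trimws(header), "#")]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.+)$", trimws(h)))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  if (is.null(meta$fps)) {
    stop(sprintf("keypoint CSV '%s' lacks a '# fps:' metadata line", path),
         call. = FALSE)
  }
  fps <- suppressWarnings(as.numeric(meta$fps))
  if (!is.finite(fps) || fps <= 0) {
    stop(sprintf("keypoint CSV '%s': fps must be > 0", path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "landmark", "x", "y", "z", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("keypoint CSV '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  n <- if (!is.null(meta$n_frames)) as.integer(meta$n_frames) else max(df$frame) + 1L
  coords <- array(NA_real_, c(n, N_LANDMARKS, 3))
  valid <- rep(FALSE, n)
  for (fi in unique(df$frame)) {
    rows <- df[df$frame == fi, , drop = FALSE]
    if (fi < 0L || fi >= n) {
      stop(sprintf("frame %d outside declared range [0, %d)", fi, n), call. = FALSE)
    }
    v <- all(as.logical(rows$valid))
    if (v && !is.null(rows$conf) && any(rows$conf < min_confidence)) v <- FALSE
    if (!v) next
    if (nrow(rows) != N_LANDMARKS || !setequal(rows$landmark, 0:20)) {
      stop(sprintf("frame %d: expected 21 landmarks 0..20, found %d rows",
                   fi, nrow(rows)), call. = FALSE)
    }
    rows <- rows[order(rows$landmark), ]
    m <- as.matrix(rows[, c("x", "y", "z")])
    if (any(!is.finite(m))) {
      stop(sprintf("frame %d: non-finite landmark coordinates", fi), call. = FALSE)
    }
    coords[fi + 1L, , ] <- m
    valid[fi + 1L] <- TRUE
  }
  hand_clip(coords, valid, fps, meta$hand_side %||% "right",
            subject_id = meta$subject_id, visit_id = meta$visit_id,
            recorded_at = meta$recorded_at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a clip to disk
#'
#' Inverse of [read_clip()]; emits the JSON or long-CSV keypoint schema.
#'
#' @inheritParams read_clip
#' @param clip a [hand_clip()].
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path, schema = c("auto", "json", "csv")) {
  stopifnot(inherits(clip, "hand_clip"))
  schema <- match.arg(schema)
  if (schema == "auto") {
    schema <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  n <- n_frames(clip)
  if (schema == "json") {
    frames <- lapply(which(clip$valid), function(i) {
      list(i = clip$frame_index[i], valid = TRUE,
           lm = lapply(seq_len(N_LANDMARKS), function(k) unname(clip$coords[i, k, ])))
    })
    obj <- list(fps = clip$fps, hand_side = clip$hand_side,
                n_frames = n, frames = frames)
    if (!is.null(clip$subject_id)) obj$subject_id <- clip$subject_id
    if (!is.null(clip$visit_id)) obj$visit_id <- clip$visit_id
    if (!is.null(clip$recorded_at)) obj$recorded_at <- as.character(clip$recorded_at)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fps: %g", clip$fps), con)
    writeLines(sprintf("# hand_side: %s", clip$hand_side), con)
    writeLines(sprintf("# n_frames: %d", n), con)
    if (!is.null(clip$subject_id)) writeLines(sprintf("# subject_id: %s", clip$subject_id), con)
    idx <- which(clip$valid)
    df <- data.frame(
      clip_id = clip$subject_id %||% "clip",
      frame = rep(clip$frame_index[idx], each = N_LANDMARKS),
      landmark = rep(0:20, length(idx)),
      x = as.vector(t(clip$coords[idx, , 1, drop = FALSE][, , 1])),
      y = as.vector(t(clip$coords[idx, , 2, drop = FALSE][, , 1])),
      z = as.vector(t(clip$coords[idx, , 3, drop = FALSE][, , 1])),
      valid = TRUE
    )
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}
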