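#' Cohort reference medians of the hand parameters
#'
#' Per item score and hand side, the median frequency (Hz), intensity (A.U.),
#' FI value (A.U./s) and peak (thumb-lengths) of a clinical finger-tapping
#' cohort, shipped with the package as a versioned CSV. These anchor the
#' severity presets of the simulator and the 80-20 radar scaling. Users
#' working with their own cohorts should supply their own medians via `path`.
#'
#' @param hand `"left"`, `"right"` or `"both"`.
#' @param path optional CSV with columns `hand, item_score, frequency,
#'   intensity, fi, peak`; defaults to the bundled file.
#' @return data.frame ordered by item score (and hand when `"both"`).
#' @export
reference_medians <- function(hand = c("left", "right", "both"), path = NULL) {
  hand <- match.arg(hand)
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_reference_medians.csv",
                        package = "fingertap", mustWork = TRUE)
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hand", "item_score", "frequency", "intensity", "fi", "peak")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("reference medians CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (hand != "both") ref <- ref[ref$hand == hand, ]
  ref[order(ref$hand, ref$item_score), ]
}
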