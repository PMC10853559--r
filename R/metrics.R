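#' Binary classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1 score and the
#' Matthews correlation coefficient (MCC), computed directly from the four
#' confusion counts. MCC is the headline binary metric here because it stays
#' informative under class imbalance. Any metric whose denominator is zero is
#' returned as 0 and flagged degenerate, so batch evaluation (e.g. grid
#' search) never aborts on a pathological fold.
#'
#' @param tp,tn,fp,fn non-negative integer confusion counts; at least one
#'   must be positive.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `mcc`, the four counts, and `degenerate` (character vector naming
#'   flagged metrics, possibly empty).
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- ratio(2 * sensitivity * precision, sensitivity + precision, "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- ratio(tp * tn - fp * fn, mcc_den, "mcc")
  list(accuracy = accuracy, sensitivity = sensitivity,
       specificity = specificity, precision = precision, f1 = f1, mcc = mcc,
       tp = tp, tn = tn, fp = fp, fn = fn, degenerate = degenerate)
}

# confusion counts of a binary prediction vector against labels (0/1)
confusion_counts <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  list(tp = sum(y == 1 & yhat == 1), tn = sum(y == 0 & yhat == 0),
       fp = sum(y == 0 & yhat == 1), fn = sum(y == 1 & yhat == 0))
}

check_scores <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop(sprintf("label (%d) and prediction (%d) vectors differ in length",
                 length(y), length(yhat)), call. = FALSE)
  }
  if (!length(y)) stop("empty score vectors", call. = FALSE)
  stopifnot(all(y %in% 0:3), all(yhat %in% 0:3))
}

#' Number of significant error files
#'
#' Count of predictions at least two ordinal steps away from the label,
#' `N_{|y - yhat| >= 2}` — the clinically serious misgradings.
#'
#' @param y,yhat equal-length item scores in `{0, 1, 2, 3}` (3 encodes 3+).
#' @return integer count.
#' @export
nse <- function(y, yhat) {
  check_scores(y, yhat)
  sum(abs(y - yhat) >= 2)
}

#' Acceptable accuracy
#'
#' Fraction of predictions within one ordinal step of the label,
#' `N_{|y - yhat| <= 1} / N`. Adjacent-score disagreement is common even
#' between human raters, so this is the headline multi-label accuracy.
#'
#' @inheritParams nse
#' @return fraction in `[0, 1]`.
#' @export
aac <- function(y, yhat) {
  check_scores(y, yhat)
  mean(abs(y - yhat) <= 1)
}

#' Cohen's kappa over the item-score categories
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_o = N_{|y - yhat| = 0} / N` and `p_e = (1 / N^2) * sum_k n_{k,y} n_{k,yhat}`,
#' marginals taken over the fixed category set `{0, 1, 2, 3+}` so that `p_e`
#' is well defined even when a class is absent from a sample. When both
#' raters are constant on the same class, `p_e = 1` and kappa is undefined;
#' that case is returned as 1 with a warning, reflecting the observed total
#' agreement.
#'
#' @inheritParams nse
#' @return coefficient in `[-1, 1]`.
#' @export
cohens_kappa <- function(y, yhat) {
  check_scores(y, yhat)
  n <- length(y)
  po <- mean(y == yhat)
  ny <- tabulate(y + 1L, nbins = 4L)
  nyh <- tabulate(yhat + 1L, nbins = 4L)
  pe <- sum(ny * nyh) / n^2
  if (pe == 1) {
    warning("both raters constant on the same class; kappa undefined, returning 1",
            call. = FALSE)
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Full agreement report for a label/prediction pair
#'
#' Bundles the multi-label agreement metrics (NSE, AAC, Cohen's kappa) with
#' exact accuracy and the per-boundary binary metric sets obtained by
#' thresholding the ordinal scores at each boundary.
#'
#' @inheritParams nse
#' @return An `agreement_report`: list with `n`, `exact_accuracy`, `nse`,
#'   `aac`, `kappa` and `boundary` (a list of [binary_metrics()] results for
#'   boundaries >= 1, >= 2, >= 3).
#' @export
agreement_report <- function(y, yhat) {
  check_scores(y, yhat)
  boundary <- lapply(1:3, function(b) {
    cc <- confusion_counts(as.integer(y >= b), as.integer(yhat >= b))
    do.call(binary_metrics, cc)
  })
  names(boundary) <- paste0("ge", 1:3)
  structure(
    list(n = length(y), exact_accuracy = mean(y == yhat), nse = nse(y, yhat),
         aac = aac(y, yhat), kappa = cohens_kappa(y, yhat), boundary = boundary),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  exact accuracy %.3f | AAC %.3f | NSE %d | kappa %.3f\n",
              x$exact_accuracy, x$aac, x$nse, x$kappa))
  for (b in names(x$boundary)) {
    m <- x$boundary[[b]]
    cat(sprintf("  boundary %s: acc %.3f, MCC %.3f, F1 %.3f\n",
                sub("ge", ">=", b), m$accuracy, m$mcc, m$f1))
  }
  invisible(x)
}
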