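# independent oracle: binary metrics recomputed from expanded label vectors,
# with MCC as the Pearson correlation of the two 0/1 vectors
oracle_binary <- function(tp, tn, fp, fn) {
  y <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  yhat <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  sens <- if (tp + fn > 0) mean(yhat[y == 1] == 1) else 0
  spec <- if (tn + fp > 0) mean(yhat[y == 0] == 0) else 0
  prec <- if (tp + fp > 0) mean(y[yhat == 1] == 1) else 0
  mcc <- suppressWarnings(stats::cor(y, yhat))
  list(accuracy = mean(y == yhat), sensitivity = sens, specificity = spec,
       precision = prec,
       f1 = if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0,
       mcc = if (is.finite(mcc)) mcc else 0)
}
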