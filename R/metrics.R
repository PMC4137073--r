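# Confusion-table performance framework: score a predicted pathway set
# against a gold standard over an explicit pathway universe.

#' Confusion table over a pathway universe
#'
#' Labels every pathway in `universe`: true positive (in both test and
#' gold), false positive (test only), false negative (gold only), true
#' negative (neither). The universe is a required input — true negatives
#' are meaningless without one.
#'
#' @param test Predicted pathway set.
#' @param gold Gold-standard pathway set.
#' @param universe Pathway universe; `test` and `gold` must be subsets.
#' @return Object of class `confusion_table`: list with `tp`, `fp`, `fn`,
#'   `tn`, `universe_size`.
#' @export
confusion_table <- function(test, gold, universe) {
  test <- unique(test); gold <- unique(gold); universe <- unique(universe)
  if (length(universe) == 0L) stop_domain("pathway universe is empty")
  out_t <- setdiff(test, universe)
  out_g <- setdiff(gold, universe)
  if (length(out_t) > 0L || length(out_g) > 0L) {
    stop_domain("pathway(s) outside the universe: %s",
                paste(utils::head(c(out_t, out_g), 5L), collapse = ", "))
  }
  tp <- length(intersect(test, gold))
  fp <- length(setdiff(test, gold))
  fn <- length(setdiff(gold, test))
  tn <- length(universe) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 universe_size = length(universe)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion_table (N = %d): TP %d, FP %d, FN %d, TN %d\n",
              x$universe_size, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Standard classification metrics from a confusion table
#'
#' Sensitivity (recall), specificity, precision, accuracy, F-measure and
#' Matthews correlation coefficient. A metric with a zero denominator is
#' reported as `NA`; MCC with a zero marginal uses the common convention of
#' 0 (flagged via attribute `mcc_zero_marginal`).
#'
#' @param ct A [confusion_table()].
#' @return Named numeric vector of the six metrics.
#' @export
metric_suite <- function(ct) {
  tp <- ct$tp; fp <- ct$fp; fn <- ct$fn; tn <- ct$tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  acc <- ratio(tp + tn, tp + fp + fn + tn)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  zero_marg <- any(marg == 0)
  mcc <- if (zero_marg) 0 else
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(marg)))
  structure(c(sensitivity = sens, specificity = spec, precision = prec,
              accuracy = acc, f_measure = f1, mcc = mcc),
            mcc_zero_marginal = zero_marg)
}

#' Pathway recovery fraction
#'
#' Fraction of the gold-standard pathways recovered by the test set —
#' identical to sensitivity, exposed under the name used for
#' coverage-vs-recovery curves.
#'
#' @param test Predicted pathway set.
#' @param gold Nonempty gold-standard pathway set.
#' @return Fraction in [0, 1].
#' @export
recovery_fraction <- function(test, gold) {
  gold <- unique(gold)
  if (length(gold) == 0L) stop_domain("gold-standard set is empty")
  length(intersect(unique(test), gold)) / length(gold)
}
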