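#' Empirical ROC curve between two samples
#'
#' Builds the empirical ROC of the rule "classify as positive when the
#' value exceeds the threshold", sweeping the threshold over the pooled
#' unique values (plus the two infinite endpoints so the curve runs from
#' (0,0) to (1,1)). Sensitivity is the positive-class exceedance
#' `Se(p) = 1 - G(p)` and specificity the negative-class CDF `Sp(p) = F(p)`.
#' The AUC is computed by the midrank Mann-Whitney statistic, which equals
#' the trapezoidal area under this curve exactly, ties included. The
#' reported operating point maximises Youden's `J = Se + Sp - 1`; ties are
#' broken toward higher specificity.
#'
#' @param negatives Numeric sample of the negative class (non-empty).
#' @param positives Numeric sample of the positive class (non-empty).
#'
#' @return An object of class `roc_result`: `thresholds` (descending),
#'   `sensitivity`, `one_minus_specificity`, `auc`, `youden_threshold`,
#'   `sensitivity_at_op`, `specificity_at_op`, `accuracy_at_op`.
#' @export
#' @examples
#' empirical_roc(c(1, 3), c(2, 4))$auc  # 0.75
empirical_roc <- function(negatives, positives) {
  if (!length(negatives) || !length(positives))
    stop_tl("both samples must be non-empty", "tl_invalid_parameter")
  thr <- c(Inf, sort(unique(c(negatives, positives)), decreasing = TRUE), -Inf)
  se <- vapply(thr, function(p) mean(positives > p), 0.0)
  fpr <- vapply(thr, function(p) mean(negatives > p), 0.0)
  sp <- 1 - fpr
  j <- se + sp - 1
  op <- which.max(j)  # first maximum = highest threshold = highest Sp
  n_pos <- length(positives); n_neg <- length(negatives)
  tp <- sum(positives > thr[op]); tn <- sum(negatives <= thr[op])
  structure(
    list(thresholds = thr, sensitivity = se, one_minus_specificity = fpr,
         auc = auc_mann_whitney(negatives, positives),
         youden_threshold = thr[op],
         sensitivity_at_op = se[op], specificity_at_op = sp[op],
         accuracy_at_op = (tp + tn) / (n_pos + n_neg)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.4f; at Youden threshold %.4g: Se = %.3f, Sp = %.3f, accuracy = %.3f\n",
    x$auc, x$youden_threshold, x$sensitivity_at_op, x$specificity_at_op,
    x$accuracy_at_op))
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' The probability that a random positive exceeds a random negative, with
#' ties counted half: `(#[pos > neg] + 0.5 #[pos == neg]) / (n_pos n_neg)`,
#' computed in O(n log n) via midranks. Identical to the trapezoidal area
#' under [empirical_roc()].
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(negatives, positives) {
  if (!length(negatives) || !length(positives))
    stop_tl("both samples must be non-empty", "tl_invalid_parameter")
  n_pos <- length(positives); n_neg <- length(negatives)
  r <- rank(c(positives, negatives))  # midranks for ties
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Pairwise power-discrimination ROC report
#'
#' For each requested pair of incident powers, treats the per-replicate
#' values at the lower power as negatives and at the higher power as
#' positives (transmittance increases with power) and reports the
#' Youden-point sensitivity, specificity, accuracy and the AUC. When a
#' pair's AUC falls below 0.5 the labels are flipped so the reported AUC is
#' `>= 0.5`, and the flip is recorded.
#'
#' @param values Data frame with columns `power_mw` and `value` (one row
#'   per replicate measurement).
#' @param pairs List of length-2 numeric vectors `c(low, high)`. Defaults
#'   to the six consecutive-power pairs of the 150-350 mW series.
#'
#' @return Data frame with columns `pair`, `power_low_mw`, `power_high_mw`,
#'   `sensitivity`, `specificity`, `auc`, `accuracy`, `flipped`.
#' @export
pairwise_power_report <- function(values,
                                  pairs = list(c(150, 200), c(200, 225),
                                               c(225, 250), c(250, 300),
                                               c(300, 350), c(150, 350))) {
  stopifnot(is.data.frame(values), all(c("power_mw", "value") %in% names(values)))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    lo <- min(pr); hi <- max(pr)
    neg <- values$value[values$power_mw == lo]
    pos <- values$value[values$power_mw == hi]
    if (!length(neg))
      stop_tl(sprintf("no values at power %g mW", lo), "tl_missing_power")
    if (!length(pos))
      stop_tl(sprintf("no values at power %g mW", hi), "tl_missing_power")
    flipped <- FALSE
    if (auc_mann_whitney(neg, pos) < 0.5) {
      tmp <- neg; neg <- pos; pos <- tmp
      flipped <- TRUE
    }
    roc <- empirical_roc(neg, pos)
    data.frame(pair = sprintf("%g and %g mW", lo, hi),
               power_low_mw = lo, power_high_mw = hi,
               sensitivity = roc$sensitivity_at_op,
               specificity = roc$specificity_at_op,
               auc = roc$auc, accuracy = roc$accuracy_at_op,
               flipped = flipped)
  })
  do.call(rbind, rows)
}
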