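#' Confusion counts for binary melanoma predictions
#'
#' Melanoma (+1) is the positive class.
#'
#' @param predicted,truth Aligned vectors of labels in `{+1, -1}`.
#' @return An `lf_confusion` list with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("`predicted` and `truth` lengths differ.")
  check_labels(predicted, "predicted")
  check_labels(truth, "truth")
  structure(
    list(tp = sum(predicted == 1 & truth == 1),
         fp = sum(predicted == 1 & truth == -1),
         tn = sum(predicted == -1 & truth == -1),
         fn = sum(predicted == -1 & truth == 1)),
    class = "lf_confusion"
  )
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

harmonic_f1 <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (a + b == 0) return(NA_real_)
  2 * a * b / (a + b)
}

#' Full metric suite from confusion counts
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative predictive
#' value, accuracy, per-class F1 and the Matthews correlation coefficient.
#' Accuracy is `(TP + TN) / (TP + FP + TN + FN)`. Metrics with a zero
#' denominator are reported as `NA` (an undefined marker), never silently 0;
#' small bootstrap test sets can legitimately have empty margins. Values are
#' kept at full precision; round only for presentation (the conventional
#' display is 2 decimals).
#'
#' @param counts An [confusion()] result.
#' @return A one-row tibble with columns `tpr`, `tnr`, `ppv`, `npv`, `acc`,
#'   `f1p`, `f1n`, `mcc`.
#' @export
metrics <- function(counts) {
  if (!inherits(counts, "lf_confusion")) abort("`counts` must come from confusion().")
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  tpr <- safe_ratio(tp, tp + fn)
  tnr <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  npv <- safe_ratio(tn, tn + fn)
  acc <- safe_ratio(tp + tn, tp + fp + tn + fn)
  denom <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) NA_real_ else (as.double(tp) * tn - as.double(fp) * fn) / sqrt(denom)
  tibble(tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, acc = acc,
         f1p = harmonic_f1(ppv, tpr), f1n = harmonic_f1(npv, tnr), mcc = mcc)
}

#' Derived metrics from the four basic rates
#'
#' Computes the per-class F1 scores and the Matthews correlation coefficient
#' directly from (TPR, TNR, PPV, NPV), without the underlying counts:
#' `F1p = 2*PPV*TPR/(PPV+TPR)`, `F1n = 2*NPV*TNR/(NPV+TNR)` and the rate
#' identity `MCC = sqrt(TPR*TNR*PPV*NPV) - sqrt((1-TPR)(1-TNR)(1-PPV)(1-NPV))`,
#' which is algebraically equal to the count formula whenever all four
#' margins are non-empty. Useful for completing published result rows that
#' report only the four rates.
#'
#' @param tpr,tnr,ppv,npv Rates in `[0, 1]`.
#' @return A one-row tibble with `f1p`, `f1n`, `mcc`.
#' @examples
#' metrics_from_rates(0.90, 0.97, 0.97, 0.90)
#' @export
metrics_from_rates <- function(tpr, tnr, ppv, npv) {
  rates <- c(tpr, tnr, ppv, npv)
  if (any(rates < 0 | rates > 1)) abort("All rates must lie in [0, 1].")
  tibble(
    f1p = harmonic_f1(ppv, tpr),
    f1n = harmonic_f1(npv, tnr),
    mcc = sqrt(tpr * tnr * ppv * npv) -
      sqrt((1 - tpr) * (1 - tnr) * (1 - ppv) * (1 - npv))
  )
}

#' Aggregate metric reports over bootstrap iterations
#'
#' Element-wise mean of every metric (ignoring undefined entries), with the
#' per-metric standard deviation retained alongside.
#'
#' @param reports A data frame of per-iteration metric rows (as produced by
#'   [run_bootstrap()]), or a list of one-row tibbles.
#' @return A one-row tibble of means plus `<metric>_sd` columns and `n_iter`.
#' @export
aggregate_metrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) reports <- dplyr::bind_rows(reports)
  if (nrow(reports) == 0L) abort("No metric reports to aggregate.")
  metric_cols <- intersect(c("tpr", "tnr", "ppv", "npv", "acc", "f1p", "f1n", "mcc"),
                           names(reports))
  means <- lapply(reports[metric_cols], mean, na.rm = TRUE)
  sds <- lapply(reports[metric_cols], stats::sd, na.rm = TRUE)
  names(sds) <- paste0(metric_cols, "_sd")
  dplyr::bind_cols(as_tibble(means), as_tibble(sds), tibble(n_iter = nrow(reports)))
}
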