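#' Classification metrics from confusion counts
#'
#' The five standard ratios: accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)` and
#' `F1 = 2*precision*recall/(precision+recall)`. A metric whose denominator
#' is zero is reported as `NA` with `defined = FALSE` rather than NaN.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; their total must be > 0.
#' @return A tibble with columns `metric`, `value`, `defined`.
#' @examples
#' classification_metrics(tp = 8, tn = 88, fp = 2, fn = 2)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Counts must be non-negative integers.", class = "psar_error_metrics")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort("At least one count must be positive.", class = "psar_error_metrics")
  }
  ratio <- function(num, den) {
    if (den > 0) list(value = num / den, defined = TRUE)
    else list(value = NA_real_, defined = FALSE)
  }
  acc <- ratio(tp + tn, total)
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (prec$defined && rec$defined && (prec$value + rec$value) > 0) {
    list(value = 2 * prec$value * rec$value / (prec$value + rec$value),
         defined = TRUE)
  } else list(value = NA_real_, defined = FALSE)
  tibble::tibble(
    metric = c("accuracy", "precision", "recall", "specificity", "f1"),
    value = c(acc$value, prec$value, rec$value, spec$value, f1$value),
    defined = c(acc$defined, prec$defined, rec$defined, spec$defined,
                f1$defined)
  )
}

#' Match detected events to ground truth by time tolerance
#'
#' Greedy one-to-one matching of detected sample indices to truth indices
#' within `tol_s` seconds, returning confusion-style counts plus the RR
#' recovery error. Used to score R-peak detection on synthetic records.
#'
#' @param detected,truth Integer sample-index vectors.
#' @param fs Sampling rate (Hz).
#' @param tol_s Matching tolerance in seconds (default 0.05).
#' @return A tibble: `n_truth`, `n_detected`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`, `mean_abs_err_ms` (over matched pairs).
#' @export
match_events <- function(detected, truth, fs, tol_s = 0.05) {
  detected <- sort(as.integer(detected))
  truth <- sort(as.integer(truth))
  tol <- tol_s * fs
  used <- logical(length(detected))
  err <- numeric(0)
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      j <- which.min(d)
      used[j] <- TRUE
      tp <- tp + 1L
      err <- c(err, abs(detected[j] - t) / fs * 1000)
    }
  }
  fp <- sum(!used)
  fn <- length(truth) - tp
  tibble::tibble(
    n_truth = length(truth), n_detected = length(detected),
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    precision = if (length(detected)) tp / length(detected) else NA_real_,
    mean_abs_err_ms = if (length(err)) mean(err) else NA_real_
  )
}
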