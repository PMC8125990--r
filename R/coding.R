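#' Extract a latency code from an output spike train
#'
#' The response code is read from the timing of the output neuron's first
#' spikes: the first latency is the time from stimulus onset to the first
#' spike, and each subsequent latency is the interval between consecutive
#' spikes.  Latencies are quantized to `bin` (round-half-up), matching the
#' whole-millisecond resolution of the reported response tables.
#'
#' @param train A [spike_train()].
#' @param k Number of latencies required (default 2).
#' @param bin Quantization bin in ms (default 1).
#' @return Numeric vector of `k` latencies, or `NULL` if the train holds
#'   fewer than `k` spikes (a no-response outcome, which classifies
#'   negative; it is not an error).
#' @examples
#' extract_latencies(spike_train(c(3, 6), 100))  # c(3, 3)
#' @export
extract_latencies <- function(train, k = 2, bin = 1) {
  stopifnot(inherits(train, "spike_train"))
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k))
  stopifnot(is.numeric(bin), length(bin) == 1L, bin > 0)
  tt <- train$times
  if (length(tt) < k) return(NULL)
  lat <- c(tt[1], diff(tt))[seq_len(k)]
  floor(lat / bin + 0.5) * bin
}

#' Squared error between a response code and the trained mode
#'
#' The classification statistic: the squared distance in latency space,
#' `(dt1 - mode1)^2 + (dt2 - mode2)^2` (generalised to `k` components).
#'
#' @param code,mode Numeric latency vectors of equal length (ms).
#' @return Squared error in ms^2.
#' @examples
#' squared_error(c(5, 7), c(3, 3))  # 20
#' @export
squared_error <- function(code, mode) {
  stopifnot(is.numeric(code), is.numeric(mode),
            length(code) == length(mode), length(code) >= 1L)
  sum((code - mode)^2)
}

#' Mean squared error of a set of response codes
#'
#' @param codes List of latency vectors.
#' @param mode Reference latency vector.
#' @return Mean of [squared_error()] over the list.
#' @export
latency_mse <- function(codes, mode) {
  if (!is.list(codes) || length(codes) < 1L)
    stop("'codes' must be a non-empty list of latency vectors")
  mean(vapply(codes, squared_error, numeric(1), mode = mode))
}

#' Threshold classification of a squared error
#'
#' A pattern is accepted as positive iff its squared error does not exceed
#' the decision threshold (ties accept, so training positives whose error
#' equals the maximum are retained).  A no-response outcome (`NA`) is
#' classified negative: a fusion event must drive the network.
#'
#' @param se Squared error(s); `NA` encodes no response.
#' @param threshold Decision bound (ms^2), >= 0.
#' @return Logical vector: `TRUE` for positive.
#' @export
classify_se <- function(se, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  !is.na(se) & se <= threshold
}

#' Confusion counts and accuracy
#'
#' @param predicted,truth Logical vectors (`TRUE` = positive).
#' @return A list of class `confusion_counts` with fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(is.logical(predicted), is.logical(truth),
            length(predicted) == length(truth), length(truth) > 0)
  structure(list(tp = sum(predicted & truth),
                 tn = sum(!predicted & !truth),
                 fp = sum(predicted & !truth),
                 fn = sum(!predicted & truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (ACC %.4f)\n",
              x$tp, x$tn, x$fp, x$fn, accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' `ACC = (TP + TN) / (TP + FN + FP + TN)`.
#'
#' @param counts A [confusion_counts()] object, or a numeric vector/list
#'   with named elements `tp`, `tn`, `fp`, `fn`.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @examples
#' accuracy(list(tp = 40, tn = 38, fp = 2, fn = 0))  # 0.975
#' @export
accuracy <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot <= 0) stop("confusion counts sum to zero")
  if (any(unlist(counts[c("tp", "tn", "fp", "fn")]) < 0))
    stop("confusion counts must be non-negative")
  (counts$tp + counts$tn) / tot
}

#' Maximum admissible sampling frequency of the input signal
#'
#' The response code must be read out before the next classification
#' window, so the maximum sampling frequency of the amperometric signal is
#' the reciprocal of the sum of the maximum latencies observed for positive
#' patterns.
#'
#' @param positive_codes Non-empty list of latency vectors (ms) from
#'   positive patterns.
#' @return Frequency in Hz.
#' @examples
#' max_sampling_frequency(list(c(3, 3), c(4, 6)))  # 100 Hz
#' @export
max_sampling_frequency <- function(positive_codes) {
  if (!is.list(positive_codes) || length(positive_codes) < 1L)
    stop("'positive_codes' must be a non-empty list")
  m <- apply(do.call(rbind, positive_codes), 2, max)
  1000 / sum(m)
}

#' Time-to-first-spike baseline classifier
#'
#' The one-latency baseline: squared error uses only the first latency, so
#' the statistic is `(dt1 - mode_dt1)^2`, reduced by exactly the second
#' component relative to the two-latency rule.  `NA` first latencies (no
#' response) classify negative.
#'
#' @param dt1 First latencies (ms), `NA` for no response.
#' @param mode_dt1 The trained first-latency mode (ms).
#' @param threshold Decision bound (ms^2).
#' @return Logical vector: `TRUE` for positive.
#' @export
first_spike_classify <- function(dt1, mode_dt1, threshold) {
  stopifnot(is.numeric(mode_dt1), length(mode_dt1) == 1L)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  se <- (dt1 - mode_dt1)^2
  !is.na(se) & se <= threshold
}
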