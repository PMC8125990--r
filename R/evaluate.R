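#' Evaluate a fitted classifier on a labelled pattern set
#'
#' Runs every pattern forward, reads its latency code, scores it against
#' the trained mode and threshold, and reports the per-pattern table
#' together with the confusion counts, accuracy, and the maximum
#' admissible sampling frequency derived from the positive responses.
#'
#' @param model A fitted `snn_fit` object.
#' @param set A [pattern_set()] with labels, or a numeric matrix plus
#'   `labels`.
#' @param labels Logical labels when `set` is a matrix.
#' @return A list of class `snn_evaluation`: `table` (per-pattern data
#'   frame), `confusion`, `accuracy`, `max_sampling_hz`.
#' @export
snn_evaluate <- function(model, set, labels = NULL) {
  stopifnot(inherits(model, "snn_fit"))
  if (inherits(set, "pattern_set")) {
    labels <- set$labels
    set <- set$patterns
  }
  labels <- as.logical(labels)
  stopifnot(is.matrix(set), length(labels) == nrow(set), !anyNA(labels))
  resp <- predict(model, set, type = "response")
  tab <- cbind(data.frame(pattern = seq_len(nrow(set))), resp,
               data.frame(label = labels))
  cc <- confusion_counts(resp$predicted, labels)
  pos_ok <- labels & !is.na(resp$dt1)
  fmax <- if (any(pos_ok)) {
    codes <- lapply(which(pos_ok), function(i)
      as.numeric(resp[i, paste0("dt", seq_len(model$k))]))
    max_sampling_frequency(codes)
  } else NA_real_
  structure(list(table = tab, confusion = cc, accuracy = accuracy(cc),
                 max_sampling_hz = fmax),
            class = "snn_evaluation")
}

#' @export
print.snn_evaluation <- function(x, ...) {
  cat("Evaluation: ")
  print(x$confusion)
  cat(sprintf("  max sampling frequency: %.3g Hz\n", x$max_sampling_hz))
  invisible(x)
}

#' Train and evaluate across a sweep of network sizes
#'
#' For each pattern size, generates a fresh benchmark, fits the
#' classifier, evaluates it on its training set, and reports the row of
#' summary quantities (neuron counts, confusion, accuracy, complexity).
#'
#' @param sizes Pattern sizes (default the 10-40 sweep in steps of 5).
#' @param n_pos,n_neg Class sizes per benchmark.
#' @param seed Base seed; size `N` uses `seed + N`.
#' @param ... Passed to [snn_fit()].
#' @return Data frame with one row per architecture.
#' @export
sweep_sizes <- function(sizes = seq(10, 40, by = 5), n_pos = 40, n_neg = 40,
                        seed = 1, ...) {
  rows <- lapply(sizes, function(n) {
    bench <- make_benchmark(n, n_pos = n_pos, n_neg = n_neg,
                            seed = seed + n)
    fit <- snn_fit(bench, ...)
    ev <- snn_evaluate(fit, bench)
    cx <- snn_complexity(n)
    data.frame(
      snn = sprintf("%d-1", n),
      ts = sum(fit$neuron_map == "tonic"),
      iis = sum(fit$neuron_map == "inhibition"),
      tp = ev$confusion$tp, tn = ev$confusion$tn,
      fp = ev$confusion$fp, fn = ev$confusion$fn,
      acc = ev$accuracy,
      complexity = sprintf("%dv + %dc", cx$n_variables, cx$n_constants)
    )
  })
  do.call(rbind, rows)
}
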