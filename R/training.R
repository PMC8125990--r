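#' Column means of a pattern subset
#'
#' @param patterns Numeric matrix, one pattern per row.
#' @param subset Row indices (or logical selector); must select at least
#'   one row.
#' @return Numeric vector of per-sample means.
#' @export
average_pattern <- function(patterns, subset = seq_len(nrow(patterns))) {
  stopifnot(is.matrix(patterns), is.numeric(patterns))
  sel <- patterns[subset, , drop = FALSE]
  if (nrow(sel) < 1L) stop("'subset' selects no patterns")
  colMeans(sel)
}

#' Analytic input-weight rule
#'
#' The one-pass, teacher-free weight mapping: `w1 = delta * (kappa - avg)`,
#' elementwise over the averaged pattern.  Samples whose running average
#' exceeds `kappa` receive negative weights and are later served by
#' inhibition-induced neurons.
#'
#' @param avg Averaged pattern (vector of per-sample means, pA).
#' @param delta Scale parameter (> 0).
#' @param kappa Offset parameter (pA).
#' @return Numeric weight vector.
#' @examples
#' compute_input_weights(c(6, 26, 65.79), delta = 1.4, kappa = 26)
#' @export
compute_input_weights <- function(avg, delta, kappa) {
  stopifnot(is.numeric(avg), all(is.finite(avg)))
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  delta * (kappa - avg)
}

#' Map input weights to neuron types
#'
#' Strictly negative weights are served by inhibition-induced neurons, all
#' others (including exact zeros, which silence the input) by tonic-spiking
#' neurons.
#'
#' @param w1 Numeric weight vector.
#' @return Character vector of `"tonic"` / `"inhibition"`.
#' @export
map_neurons <- function(w1) {
  stopifnot(is.numeric(w1), all(is.finite(w1)))
  ifelse(w1 < 0, "inhibition", "tonic")
}

#' Heuristic learning parameters for a given pattern size
#'
#' There is no analytic rule for the learning parameters; they scale with
#' the input-layer size as `kappa ~ N` and `delta ~ 1/N`.  This helper
#' anchors the proportionality at the reference 20-input configuration
#' (`delta = 1.4`, `kappa = 26`) and clips to the published operating
#' ranges (`delta` in 0.95-1.4, `kappa` in 26-32) inside the calibrated
#' span of N = 10-40; outside that span it extrapolates with a warning.
#'
#' @param n_inputs Pattern size `N`.
#' @return List with `delta` and `kappa`.
#' @examples
#' suggest_delta_kappa(20)  # delta 1.4, kappa 26
#' @export
suggest_delta_kappa <- function(n_inputs) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1L || n_inputs < 1)
    stop("'n_inputs' must be a single integer >= 1")
  n <- as.numeric(n_inputs)
  if (n < 10 || n > 40)
    warning("suggest_delta_kappa() is calibrated for N in 10..40; ",
            "extrapolating")
  delta <- min(max(1.4 * 20 / n, 0.95), 1.4)
  kappa <- min(max(26 * n / 20, 26), 32)
  list(delta = delta, kappa = kappa)
}

#' Calibrate the input coupling factor
#'
#' Scans a geometric grid of gains.  A gain is feasible when every positive
#' training pattern elicits at least `min_spikes` output spikes inside the
#' simulation window (the training self-check); among feasible gains the
#' calibration returns the one whose positive latency codes cluster most
#' tightly around their own per-component mode (smallest maximum squared
#' error), breaking ties toward the smaller gain.  Tight positive clusters
#' give a small decision threshold, which is what the latency code's
#' selectivity rests on.  Only positive patterns are consulted, so the
#' calibration is as teacher-free as the weight rule itself.
#'
#' The output spike count is not monotone in the gain: an over-driven
#' first-layer neuron fires at every Euler step, its transmitted trace
#' saturates, and its synapse falls silent.  The scan therefore evaluates
#' the whole grid rather than stopping at the first feasible point.
#'
#' @param patterns Numeric matrix of training patterns (rows).
#' @param positive Logical vector marking positive rows.
#' @param w1 Input weights from [compute_input_weights()].
#' @param gains Candidate grid (default geometric, 0.05 to about 50).
#' @param min_spikes Required output spikes per positive pattern
#'   (default 2, the two-latency code).
#' @param latency_bin Quantization used when scoring tightness (ms).
#' @inheritParams snn_network
#' @return The calibrated gain (scalar).
#' @export
calibrate_input_gain <- function(patterns, positive, w1,
                                 gains = 0.05 * 1.1^(0:72),
                                 min_spikes = 2, latency_bin = 1,
                                 w2 = 0.0025, c_ref = 0.0083, dt = 0.1,
                                 duration = 100, zero_reset_deriv = TRUE) {
  stopifnot(is.matrix(patterns), is.logical(positive),
            length(positive) == nrow(patterns), any(positive))
  pos <- patterns[positive, , drop = FALSE]
  k <- as.integer(min_spikes)
  best_g <- NA_real_
  best_spread <- Inf
  for (g in sort(gains)) {
    net <- snn_network(w1, w2 = w2, c_ref = c_ref, input_gain = g,
                       dt = dt, duration = duration,
                       zero_reset_deriv = zero_reset_deriv)
    codes <- vector("list", nrow(pos))
    ok <- TRUE
    for (i in seq_len(nrow(pos))) {
      cd <- extract_latencies(snn_forward(net, pos[i, ]), k = k,
                              bin = latency_bin)
      if (is.null(cd)) { ok <- FALSE; break }
      codes[[i]] <- cd
    }
    if (!ok) next
    mode <- vapply(seq_len(k), function(j) {
      vals <- vapply(codes, `[`, numeric(1), j)
      tab <- table(vals)
      min(as.numeric(names(tab)[tab == max(tab)]))
    }, numeric(1))
    spread <- max(vapply(codes, squared_error, numeric(1), mode = mode))
    if (spread < best_spread) {
      best_spread <- spread
      best_g <- g
    }
  }
  if (is.na(best_g))
    stop("input-gain calibration failed: no gain in the scanned grid makes ",
         "every positive training pattern elicit ", min_spikes,
         " output spikes; consider adjusting delta/kappa or the grid")
  best_g
}

#' Fit the linear-complexity spiking-network classifier
#'
#' One-pass, teacher-free training: average the positive reference
#' patterns, map the input weights analytically with
#' [compute_input_weights()], assign neuron types by weight sign, attach
#' the shared output weight and synapse capacitance, then run every
#' training pattern forward once to read the two-latency response code.
#' The trained response mode is the per-component mode of the quantized
#' positive-pattern latencies (ties break toward the earlier response) and
#' the decision threshold is the largest squared error among positive
#' training patterns.  No iterative updates occur; each pattern is touched
#' a constant number of times, and the only data-dependent parameters of
#' the fitted model are the `N` input weights.
#'
#' Labels enter only through the choice of reference class, the decision
#' threshold and the reported training accuracy; the weight rule itself is
#' unsupervised.
#'
#' @param x Training patterns: a numeric matrix (one pattern per row) or a
#'   [pattern_set()].
#' @param labels Logical (or 0/1) vector of class labels, `TRUE` =
#'   positive (fusion).  Ignored when `x` is a `pattern_set`.
#' @param delta,kappa Learning parameters; default from
#'   [suggest_delta_kappa()].
#' @param input_gain Either a positive scalar or `"auto"` (default) to run
#'   [calibrate_input_gain()].
#' @param latency_bin Latency quantization in ms (default 1).
#' @param k Number of latencies in the response code (default 2).
#' @param average_all If `TRUE`, average every training pattern (the
#'   strict reading of the mapping algorithm) instead of positives only.
#' @param standardize If `TRUE` (default), clip patterns at zero so all
#'   input currents are non-negative.
#' @inheritParams snn_network
#' @return An object of class `c("snn_fit", "snn_network")`, with the
#'   network fields plus `code_mode`, `se_threshold`, `delta`, `kappa`,
#'   `latency_bin`, `k` and a per-pattern `training` data frame.
#' @examples
#' \donttest{
#' bench <- make_benchmark(n_samples = 20, seed = 1)
#' fit <- snn_fit(bench)
#' summary(fit)
#' }
#' @export
snn_fit <- function(x, labels = NULL, delta = NULL, kappa = NULL,
                    input_gain = "auto", latency_bin = 1, k = 2,
                    average_all = FALSE, standardize = TRUE,
                    w2 = 0.0025, c_ref = 0.0083, dt = 0.1, duration = 100,
                    zero_reset_deriv = TRUE) {
  if (inherits(x, "pattern_set")) {
    labels <- x$labels
    x <- x$patterns
  }
  stopifnot(is.matrix(x), is.numeric(x), nrow(x) >= 1L)
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(x), !anyNA(labels), any(labels))
  if (standardize) x <- pmax(x, 0)
  n <- ncol(x)

  if (is.null(delta) || is.null(kappa)) {
    sug <- suggest_delta_kappa(n)
    if (is.null(delta)) delta <- sug$delta
    if (is.null(kappa)) kappa <- sug$kappa
  }
  avg <- average_pattern(x, if (average_all) seq_len(nrow(x)) else
    which(labels))
  w1 <- compute_input_weights(avg, delta, kappa)

  if (identical(input_gain, "auto")) {
    input_gain <- calibrate_input_gain(x, labels, w1, min_spikes = k,
                                       latency_bin = latency_bin, w2 = w2,
                                       c_ref = c_ref, dt = dt,
                                       duration = duration,
                                       zero_reset_deriv = zero_reset_deriv)
  }
  net <- snn_network(w1, w2 = w2, c_ref = c_ref, input_gain = input_gain,
                     dt = dt, duration = duration,
                     zero_reset_deriv = zero_reset_deriv)

  codes <- lapply(seq_len(nrow(x)), function(i)
    extract_latencies(snn_forward(net, x[i, ]), k = k, bin = latency_bin))
  pos_codes <- codes[labels]
  if (any(vapply(pos_codes, is.null, logical(1))))
    stop("calibration failure: ", sum(vapply(pos_codes, is.null, logical(1))),
         " positive training pattern(s) elicited fewer than ", k,
         " output spikes within the window; increase input_gain or adjust ",
         "delta/kappa")
  code_mode <- vapply(seq_len(k), function(j) {
    vals <- vapply(pos_codes, `[`, numeric(1), j)
    tab <- table(vals)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    min(cand)  # ties break toward the earlier response
  }, numeric(1))

  se <- vapply(codes, function(cd)
    if (is.null(cd)) NA_real_ else squared_error(cd, code_mode), numeric(1))
  se_threshold <- max(se[labels])

  model <- net
  model$code_mode <- code_mode
  model$se_threshold <- se_threshold
  model$delta <- delta
  model$kappa <- kappa
  model$latency_bin <- latency_bin
  model$k <- as.integer(k)
  model$average_all <- isTRUE(average_all)
  class(model) <- c("snn_fit", "snn_network")

  lat <- t(vapply(codes, function(cd)
    if (is.null(cd)) rep(NA_real_, k) else cd, numeric(k)))
  colnames(lat) <- paste0("dt", seq_len(k))
  model$training <- data.frame(pattern = seq_len(nrow(x)), lat, se = se,
                               predicted = classify_se(se, se_threshold),
                               label = labels)
  model
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf(
    "Trained %d-1 spiking-network classifier\n", x$n_inputs))
  cat(sprintf("  neurons: %d tonic, %d inhibition-induced\n",
              sum(x$neuron_map == "tonic"),
              sum(x$neuron_map == "inhibition")))
  cat(sprintf("  delta = %g, kappa = %g, input gain = %g\n",
              x$delta, x$kappa, x$input_gain))
  cat(sprintf("  response mode = (%s) ms, SE threshold = %g ms^2\n",
              paste(x$code_mode, collapse = ", "), x$se_threshold))
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  tr <- object$training
  cc <- confusion_counts(tr$predicted, tr$label)
  pos_codes <- lapply(which(tr$label), function(i)
    as.numeric(tr[i, paste0("dt", seq_len(object$k))]))
  out <- list(
    model = object,
    confusion = cc,
    accuracy = accuracy(cc),
    w1_range_tonic = range(object$w1[object$neuron_map == "tonic"]),
    w1_range_inhibition =
      if (any(object$neuron_map == "inhibition"))
        range(object$w1[object$neuron_map == "inhibition"]) else NULL,
    max_positive_se = max(tr$se[tr$label]),
    min_negative_se = if (any(!tr$label))
      suppressWarnings(min(tr$se[!tr$label], na.rm = TRUE)) else NULL,
    max_sampling_hz = max_sampling_frequency(pos_codes),
    complexity = snn_complexity(object$n_inputs)
  )
  if (is.infinite(out$min_negative_se %||% 0))
    out$min_negative_se <- Inf  # every negative was a no-response
  class(out) <- "summary.snn_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.snn_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  tonic weights in [%.2f, %.2f]\n",
              x$w1_range_tonic[1], x$w1_range_tonic[2]))
  if (!is.null(x$w1_range_inhibition))
    cat(sprintf("  inhibition weights in [%.2f, %.2f]\n",
                x$w1_range_inhibition[1], x$w1_range_inhibition[2]))
  cat("  training ");  print(x$confusion)
  cat(sprintf("  max positive SE %g; min negative SE %s\n",
              x$max_positive_se,
              if (is.null(x$min_negative_se)) "n/a"
              else format(x$min_negative_se)))
  cat(sprintf("  max sampling frequency %.3g Hz; complexity %dv + %dc\n",
              x$max_sampling_hz, x$complexity$n_variables,
              x$complexity$n_constants))
  invisible(x)
}

#' @export
coef.snn_fit <- function(object, ...) {
  c(stats::setNames(object$w1, paste0("w1.", seq_along(object$w1))),
    w2 = object$w2)
}

#' Classify new patterns with a fitted network
#'
#' @param object A fitted `snn_fit` model.
#' @param newdata Numeric matrix of patterns (rows), a single pattern
#'   vector, or a [pattern_set()].
#' @param type `"class"` for logical predictions, `"response"` for a data
#'   frame with latencies, squared error and prediction.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.snn_fit <- function(object, newdata,
                            type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "pattern_set")) newdata <- newdata$patterns
  if (is.vector(newdata) && is.numeric(newdata))
    newdata <- matrix(newdata, nrow = 1)
  stopifnot(is.matrix(newdata), ncol(newdata) == object$n_inputs)
  k <- object$k
  codes <- lapply(seq_len(nrow(newdata)), function(i)
    extract_latencies(snn_forward(object, newdata[i, ]), k = k,
                      bin = object$latency_bin))
  se <- vapply(codes, function(cd)
    if (is.null(cd)) NA_real_ else squared_error(cd, object$code_mode),
    numeric(1))
  pred <- classify_se(se, object$se_threshold)
  if (type == "class") return(pred)
  lat <- t(vapply(codes, function(cd)
    if (is.null(cd)) rep(NA_real_, k) else cd, numeric(k)))
  colnames(lat) <- paste0("dt", seq_len(k))
  data.frame(lat, se = se, predicted = pred)
}

#' Per-pattern squared-error residuals of the training set
#'
#' @param object A fitted `snn_fit` model.
#' @param ... Unused.
#' @return Numeric vector of training squared errors (`NA` = no response).
#' @export
residuals.snn_fit <- function(object, ...) {
  stats::setNames(object$training$se, object$training$pattern)
}

#' Plot the training response codes of a fitted network
#'
#' Scatter of the two response latencies for every training pattern,
#' positives and negatives distinguished, with the trained mode marked.
#'
#' @param x A fitted `snn_fit` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.snn_fit <- function(x, ...) {
  tr <- x$training
  jit <- function(v) v + stats::runif(length(v), -0.15, 0.15)
  ok <- !is.na(tr$dt1)
  graphics::plot(jit(tr$dt1[ok]), jit(tr$dt2[ok]),
                 col = ifelse(tr$label[ok], "#1b7837", "#762a83"),
                 pch = ifelse(tr$label[ok], 19, 4),
                 xlab = expression(Delta * t[1] ~ "(ms)"),
                 ylab = expression(Delta * t[2] ~ "(ms)"), ...)
  graphics::points(x$code_mode[1], x$code_mode[2], pch = 8, cex = 2,
                   col = "black")
  graphics::legend("topright",
                   legend = c("positive", "negative", "mode"),
                   col = c("#1b7837", "#762a83", "black"),
                   pch = c(19, 4, 8), bty = "n")
  invisible(x)
}
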