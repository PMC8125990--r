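#' Perturb the synaptic weights of a trained model
#'
#' Emulates fabrication mismatch in a hardware implementation: every input
#' weight and the shared output weight are randomly rescaled.  In
#' `"systematic"` mode (the default, reflecting the gradient character of
#' process variation across a common substrate) each weight is multiplied
#' by `1 + u * percent/100` with `u ~ Uniform(0, 1)`, so all deviations
#' share the sign of `percent`.  In `"independent"` mode the factor is
#' `1 + Uniform(-1, 1) * |percent|/100`.  The neuron-type map is never
#' remapped: fabricated hardware keeps its neuron types.  The trained
#' response mode and threshold are left untouched.
#'
#' @param model A fitted `snn_fit` object.
#' @param percent Signed mismatch percentage.
#' @param mode `"systematic"` or `"independent"`.
#' @return A perturbed copy of `model`.
#' @export
perturb_weights <- function(model, percent,
                            mode = c("systematic", "independent")) {
  stopifnot(inherits(model, "snn_fit"))
  mode <- match.arg(mode)
  stopifnot(is.numeric(percent), length(percent) == 1L, is.finite(percent))
  n <- model$n_inputs
  fac <- if (mode == "systematic") {
    1 + stats::runif(n + 1) * percent / 100
  } else {
    1 + stats::runif(n + 1, -1, 1) * abs(percent) / 100
  }
  model$w1 <- model$w1 * fac[seq_len(n)]
  model$w2 <- model$w2 * fac[n + 1]
  model
}

#' Accuracy versus weight-mismatch sweep
#'
#' For each percentage on the grid, draws `samples_per_point` perturbed
#' copies of the trained model and evaluates each on the labelled set with
#' the frozen trained mode and threshold, recording the mean and extreme
#' accuracies.  Perturbation never re-triggers training.
#'
#' @param model A fitted `snn_fit` object.
#' @param set Labelled [pattern_set()] (or matrix with `labels`).
#' @param percents Signed percentage grid (default -30 to +10).
#' @param samples_per_point Draws per grid point (default 50).
#' @param mode Perturbation mode, see [perturb_weights()].
#' @param seed Optional seed for the perturbation stream.
#' @param labels Labels when `set` is a matrix.
#' @param correction Optional pre-scaling factor applied to all weights
#'   before the sweep (a fabrication countermeasure; e.g. 1.1 applies a
#'   +10 percent correction).
#' @return Data frame with `percent`, `mean_acc`, `min_acc`, `max_acc`.
#' @export
mismatch_sweep <- function(model, set, percents = c(-30, -20, -10, -5, -2,
                                                    0, 2, 5, 10),
                           samples_per_point = 50,
                           mode = c("systematic", "independent"),
                           seed = NULL, labels = NULL, correction = 1) {
  stopifnot(inherits(model, "snn_fit"), samples_per_point >= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(set, "pattern_set")) {
    labels <- set$labels
    set <- set$patterns
  }
  if (correction != 1) {
    model$w1 <- model$w1 * correction
    model$w2 <- model$w2 * correction
  }
  rows <- lapply(percents, function(p) {
    acc <- vapply(seq_len(samples_per_point), function(i) {
      pm <- perturb_weights(model, p, mode)
      snn_evaluate(pm, set, labels)$accuracy
    }, numeric(1))
    data.frame(percent = p, mean_acc = mean(acc), min_acc = min(acc),
               max_acc = max(acc))
  })
  do.call(rbind, rows)
}
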