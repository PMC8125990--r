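#' Construct an N-1 spiking network
#'
#' Assembles the feed-forward topology used throughout the package: `N`
#' weighted inputs, `N` first-layer neurons whose type follows the sign of
#' the input weight (negative weight, inhibition-induced; otherwise tonic
#' spiking), and identical capacitive synapses from every first-layer neuron
#' into a single tonic-spiking output neuron.  All between-layer weights
#' share the single scalar `w2` (zero dispersion) and all synapse
#' capacitances share `c_ref`; neither changes during training.
#'
#' Each input sample is held as a constant drive `input_gain * w1[i] * x[i]`
#' for the whole simulation window, mirroring an analog front-end that
#' presents one static N-wide sample bus per classification window.
#'
#' @param w1 Numeric vector of `N` signed input weights.
#' @param w2 Shared output-layer weight (default 0.0025).
#' @param c_ref Shared synapse capacitance (default 0.0083).
#' @param input_gain Scalar coupling factor applied to all input drives.
#'   The published weight magnitudes multiplied by pA-scale samples can land
#'   far outside the neuron model's depicted operating range, so deployments
#'   calibrate this factor (see [calibrate_input_gain()]); the constructor
#'   default of 1 is the literal reading.
#' @param dt Euler step in ms (default 0.1).
#' @param duration Simulation window in ms (default 100; long enough to
#'   contain response latencies in the tens of ms with margin).
#' @param zero_reset_deriv Suppress the synaptic derivative term across
#'   presynaptic reset steps (default `TRUE`; see [synapse_current()]).
#' @return An object of class `snn_network`.
#' @export
snn_network <- function(w1, w2 = 0.0025, c_ref = 0.0083, input_gain = 1,
                        dt = 0.1, duration = 100, zero_reset_deriv = TRUE) {
  stopifnot(is.numeric(w1), length(w1) >= 1L, all(is.finite(w1)))
  stopifnot(is.numeric(w2), length(w2) == 1L, is.finite(w2))
  stopifnot(is.numeric(c_ref), length(c_ref) == 1L, c_ref >= 0)
  stopifnot(is.numeric(input_gain), length(input_gain) == 1L, input_gain > 0)
  stopifnot(dt > 0, duration > 0)
  structure(list(
    n_inputs = length(w1),
    w1 = as.numeric(w1),
    neuron_map = map_neurons(w1),
    w2 = as.numeric(w2),
    c_ref = as.numeric(c_ref),
    input_gain = as.numeric(input_gain),
    dt = as.numeric(dt),
    duration = as.numeric(duration),
    zero_reset_deriv = isTRUE(zero_reset_deriv)
  ), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("%d-1 spiking network: %d tonic / %d inhibition-induced,\n",
              x$n_inputs, sum(x$neuron_map == "tonic"),
              sum(x$neuron_map == "inhibition")))
  cat(sprintf("  w2 = %g, Cref = %g, input gain = %g, dt = %g ms, window = %g ms\n",
              x$w2, x$c_ref, x$input_gain, x$dt, x$duration))
  invisible(x)
}

#' Run one pattern through the network
#'
#' Drives first-layer neuron `i` with the constant current
#' `input_gain * w1[i] * x[i]` (clamped at zero for tonic neurons when
#' negative), passes every first-layer voltage trace through its capacitive
#' synapse, sums the synaptic currents (the sum is clamped at zero because
#' the output neuron is tonic spiking) and integrates the output neuron.
#' Deterministic: identical model, pattern and step give identical trains.
#'
#' @param model An `snn_network` (or fitted `snn_fit`) object.
#' @param pattern Numeric vector of `N` current samples (pA).
#' @return A [spike_train()] with the output neuron's spike times.
#' @export
snn_forward <- function(model, pattern) {
  stopifnot(inherits(model, "snn_network"))
  if (!is.numeric(pattern) || length(pattern) != model$n_inputs)
    stop(sprintf("pattern has %d samples but the network expects N = %d",
                 length(pattern), model$n_inputs))
  if (!all(is.finite(pattern))) stop("pattern contains non-finite samples")
  K <- as.integer(round(model$duration / model$dt))
  times <- .snn_forward_cpp(model$w1,
                            as.integer(model$neuron_map == "inhibition"),
                            as.numeric(pattern), model$input_gain, model$w2,
                            model$c_ref, model$dt, K,
                            model$zero_reset_deriv)
  spike_train(times, model$duration)
}

#' Algorithmic complexity of the N-1 architecture
#'
#' The trained network stores exactly `N` data-dependent parameters (the
#' input weights) and `4N + 6` constants: four Izhikevich constants per
#' first-layer neuron, plus the shared output weight, capacitance and the
#' four constants of the output neuron.  Complexity is therefore linear in
#' the pattern size.
#'
#' @param n_inputs Pattern size `N` (>= 1).
#' @return A list with `n_variables` (= N) and `n_constants` (= 4N + 6).
#' @examples
#' snn_complexity(20)  # 20 variables, 86 constants
#' @export
snn_complexity <- function(n_inputs) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1L || n_inputs < 1 ||
      n_inputs != round(n_inputs))
    stop("'n_inputs' must be a single integer >= 1")
  n <- as.integer(n_inputs)
  list(n_variables = n, n_constants = 4L * n + 6L)
}

#' Serialize a network or fitted model to JSON
#'
#' @param model An `snn_network` or `snn_fit` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "snn_network"))
  obj <- unclass(model)
  obj$schema <- "spikeamp-model-1"
  obj$classes <- class(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a network or fitted model from JSON
#'
#' @param path File written by [write_model()].
#' @return The restored object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "spikeamp-model"))
    stop("not a spikeamp model file: ", path)
  cls <- obj$classes
  obj$schema <- NULL
  obj$classes <- NULL
  for (f in c("w1", "neuron_map")) obj[[f]] <- as.vector(obj[[f]])
  if (!is.null(obj$code_mode)) obj$code_mode <- as.numeric(obj$code_mode)
  structure(obj, class = cls)
}
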