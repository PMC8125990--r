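#' Capacitive synapse: voltage trace to postsynaptic current
#'
#' Models synaptic transmission as the sum of a resistive and a capacitive
#' current,
#' \deqn{I_{soma} = V/R + C_{ref}\, dV/dt,}
#' where the resistance is the reciprocal of the synaptic weight, so the
#' resistive term is `weight * V`.  The derivative is realised as a backward
#' first difference at the simulation step (the simplest causal estimator an
#' online hardware synapse could implement): for sample `k >= 2` the output
#' is `weight * V[k] + c_ref * (V[k] - V[k-1]) / dt`, and the first sample
#' has no derivative available, so `out[1] = weight * V[1]`.
#'
#' Negative weights are legal (inhibition-induced presynaptic neurons are
#' paired with them in the input layer).
#'
#' @param v_pre Presynaptic membrane-voltage trace (mV), at least 2 samples.
#' @param weight Conductance-like gain; reciprocal of the synapse resistance.
#' @param c_ref Synapse capacitance in model units (default 0.0083, shared
#'   by every synapse in the network).
#' @param dt Sampling step of the trace in ms.
#' @param reset_steps Optional integer indices of samples lying immediately
#'   after a presynaptic post-spike reset; the derivative term is suppressed
#'   there so that the reset discontinuity (about -95 mV in one step) is not
#'   transmitted as a spurious current pulse.  `NULL` keeps the literal
#'   finite difference everywhere.
#' @return Numeric vector of postsynaptic current, same length as `v_pre`.
#' @examples
#' synapse_current(c(0, 1), weight = 1, c_ref = 0.0083, dt = 1)
#' @export
synapse_current <- function(v_pre, weight = 0.0025, c_ref = 0.0083, dt,
                            reset_steps = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (!is.numeric(v_pre) || length(v_pre) < 2L)
    stop("'v_pre' must be a numeric trace with at least 2 samples")
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight))
  stopifnot(is.numeric(c_ref), length(c_ref) == 1L, c_ref >= 0)
  der <- c(0, diff(v_pre) / dt)
  if (!is.null(reset_steps)) {
    reset_steps <- as.integer(reset_steps)
    stopifnot(all(reset_steps >= 1L), all(reset_steps <= length(v_pre)))
    der[reset_steps] <- 0
  }
  weight * v_pre + c_ref * der
}
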