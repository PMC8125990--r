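#' Izhikevich neuron parameter sets
#'
#' Returns the constants \eqn{(a, b, c, d)} of the two-variable Izhikevich
#' model for the two firing regimes used by the network: tonic spiking (TS)
#' and inhibition-induced spiking (IIS).  Tonic-spiking neurons fire regular
#' spikes under sustained positive input current and are only valid for
#' non-negative currents; inhibition-induced neurons are complementary, with
#' a firing rate that increases as the input current becomes more negative.
#'
#' The model is
#' \deqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I_{app}}
#' \deqn{du/dt = a (b v - u)}
#' with the post-spike reset \eqn{v \ge 30 \Rightarrow v \leftarrow c,\;
#' u \leftarrow u + d}.  Coefficients assume \eqn{v} in mV and \eqn{t} in ms.
#'
#' @param kind `"tonic"` or `"inhibition"` (abbreviations allowed).
#' @param b Recovery-sensitivity constant; overridable because published
#'   tonic-spiking variants differ in this constant, the firing profile
#'   (regular spiking under sustained positive current) being the arbiter.
#' @return An object of class `izh_params`: a list with fields `a`, `b`,
#'   `c`, `d` and `kind`.
#' @examples
#' izh_params("tonic")
#' izh_params("inhibition")
#' @export
izh_params <- function(kind = c("tonic", "inhibition"), b = NULL) {
  kind <- match.arg(kind)
  p <- if (kind == "tonic") {
    list(a = 0.02, b = -0.1, c = -65, d = 6, kind = "tonic")
  } else {
    list(a = -0.02, b = -1, c = -60, d = 8, kind = "inhibition")
  }
  if (!is.null(b)) {
    stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
    p$b <- b
  }
  structure(p, class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich %s-spiking parameters: a=%g b=%g c=%g d=%g\n",
              if (x$kind == "tonic") "tonic" else "inhibition-induced",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' One forward-Euler step of the Izhikevich model
#'
#' Advances the state \eqn{(v, u)} by one time step `dt` under applied
#' current `i_app`, then applies the post-spike reset if the updated
#' membrane potential has reached the +30 mV apex.  The update order is:
#' update `v` and `u` first, then test `v >= 30`.
#'
#' @param state Numeric vector `c(v, u)` (membrane potential mV, recovery).
#' @param params An [izh_params()] object.
#' @param i_app Applied current for this step (pA-scale model units).
#' @param dt Time step in ms; must be positive.
#' @return A list with `state` (the updated `c(v, u)`) and `spiked` (flag).
#' @examples
#' p <- izh_params("tonic")
#' izh_step(c(-65, 6.5), p, i_app = 10, dt = 0.1)
#' @export
izh_step <- function(state, params, i_app, dt) {
  stopifnot(inherits(params, "izh_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (!is.numeric(state) || length(state) != 2L || !all(is.finite(state)))
    stop("'state' must be a finite numeric vector c(v, u)")
  if (!is.numeric(i_app) || length(i_app) != 1L || !is.finite(i_app))
    stop("'i_app' must be a single finite number")
  v <- state[[1]]; u <- state[[2]]
  nv <- v + dt * (0.04 * v * v + 5 * v + 140 - u + i_app)
  nu <- u + dt * params$a * (params$b * v - u)
  if (nv >= 30) {
    list(state = c(v = params$c, u = nu + params$d), spiked = TRUE)
  } else {
    list(state = c(v = nv, u = nu), spiked = FALSE)
  }
}

#' Simulate a single Izhikevich neuron
#'
#' Integrates the model with the forward-Euler map at fixed `dt` and returns
#' the emitted spike train.  For tonic-spiking parameters any negative
#' instantaneous current is clamped to zero before integration (the regime
#' is only valid for positive input currents); inhibition-induced neurons
#' receive the signed current unchanged.
#'
#' A trajectory that remains beyond the +/-500 mV guard for more than
#' `patience` consecutive sub-threshold steps aborts with a diagnostic;
#' transient Euler excursions that terminate in a spike are legitimate
#' behaviour of the discrete map and do not trigger the guard.
#'
#' @param params An [izh_params()] object.
#' @param current Either a single constant current or a numeric vector with
#'   one value per time step covering `[0, duration]`.
#' @param duration Simulated span in ms.
#' @param dt Euler step in ms (default 0.1).
#' @param init Optional `c(v0, u0)`; defaults to the conventional resting
#'   initialisation `v0 = c`, `u0 = b * v0`.
#' @param keep_trace If `TRUE`, attach the per-step transmitted voltage
#'   trace (spike apices clamped at +30 mV) as attribute `"trace"`.
#' @return A [spike_train()] object.
#' @examples
#' st <- izh_simulate(izh_params("tonic"), current = 40, duration = 200)
#' length(st$times)
#' @export
izh_simulate <- function(params, current, duration, dt = 0.1, init = NULL,
                         keep_trace = FALSE) {
  stopifnot(inherits(params, "izh_params"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive number")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  K <- as.integer(round(duration / dt))
  if (K < 1L) stop("'duration' must cover at least one step of size 'dt'")
  if (!is.numeric(current) || !all(is.finite(current)))
    stop("'current' must be finite numeric")
  if (length(current) == 1L) {
    current <- rep(as.numeric(current), K)
  } else if (length(current) < K) {
    stop(sprintf("'current' series has %d samples but %d steps are needed",
                 length(current), K))
  } else {
    current <- as.numeric(current[seq_len(K)])
  }
  if (is.null(init)) init <- c(params$c, params$b * params$c)
  stopifnot(is.numeric(init), length(init) == 2L, all(is.finite(init)))
  res <- .izh_simulate_cpp(params$a, params$b, params$c, params$d,
                           current, dt, init[[1]], init[[2]],
                           clamp_negative = params$kind == "tonic")
  st <- spike_train(res$times, duration)
  if (keep_trace) attr(st, "trace") <- res$trace
  st
}

#' Spike-train container
#'
#' @param times Strictly increasing spike times in ms, all within
#'   `[0, duration]`.
#' @param duration Simulated span in ms.
#' @return An object of class `spike_train` (list with `times`, `duration`).
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(length(duration) == 1L, duration > 0)
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g ms", length(x$times),
              x$duration))
  if (length(x$times))
    cat(sprintf(" (first at %g ms)", x$times[1]))
  cat("\n")
  invisible(x)
}

#' Firing-rate response to a grid of constant currents
#'
#' Convenience wrapper producing the f-I characteristic of one neuron type:
#' the number of spikes in a fixed window for each probe current.
#'
#' @param kind `"tonic"` or `"inhibition"`.
#' @param currents Numeric vector of constant probe currents (pA).
#' @param duration Window in ms (default 500).
#' @param dt Euler step in ms.
#' @return A data frame with columns `current`, `spikes`, `rate_hz`.
#' @export
neuron_fi <- function(kind, currents, duration = 500, dt = 0.1) {
  p <- izh_params(kind)
  n <- vapply(currents, function(i)
    length(izh_simulate(p, i, duration, dt)$times), numeric(1))
  data.frame(current = currents, spikes = n, rate_hz = 1000 * n / duration)
}
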