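# Shared fixtures and independent reference implementations used as oracles.

# Pure-R forward pass, written independently of the compiled path (plain
# per-step loops via izh_step plus explicit synapse arithmetic).  Used to
# cross-check the C++ network simulation.
ref_forward <- function(model, pattern) {
  N <- model$n_inputs
  K <- round(model$duration / model$dt)
  dt <- model$dt
  prm <- lapply(model$neuron_map, function(k)
    izh_params(if (k == "inhibition") "inhibition" else "tonic"))
  drive <- model$input_gain * model$w1 * pattern
  for (i in seq_len(N))
    if (model$neuron_map[i] == "tonic" && drive[i] < 0) drive[i] <- 0
  st <- lapply(prm, function(p) c(p$c, p$b * p$c))
  vprev <- vapply(st, `[`, numeric(1), 1)
  lastsp <- rep(FALSE, N)
  po <- izh_params("tonic")
  so <- c(po$c, po$b * po$c)
  out <- numeric(0)
  for (k in seq_len(K)) {
    itot <- 0
    for (i in seq_len(N)) {
      r <- izh_step(st[[i]], prm[[i]], drive[i], dt)
      tr <- if (r$spiked) 30 else r$state[[1]]
      der <- (tr - vprev[i]) / dt
      if (model$zero_reset_deriv && lastsp[i]) der <- 0
      itot <- itot + model$w2 * tr + model$c_ref * der
      st[[i]] <- r$state
      vprev[i] <- tr
      lastsp[i] <- r$spiked
    }
    if (itot < 0) itot <- 0
    ro <- izh_step(so, po, itot, dt)
    so <- ro$state
    if (ro$spiked) out <- c(out, k * dt)
  }
  out
}

# Brute-force squared error: explicit element loop, no vectorisation.
ref_squared_error <- function(code, mode) {
  s <- 0
  for (j in seq_along(code)) s <- s + (code[j] - mode[j])^2
  s
}

# Per-column mean via an explicit double loop.
ref_column_means <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    acc <- 0
    for (i in seq_len(nrow(m))) acc <- acc + m[i, j]
    out[j] <- acc / nrow(m)
  }
  out
}

# The canonical study conditions used by the end-to-end tests: the standard
# 40+40 benchmark at N = 20, seed 1, fitted with suggested parameters and
# calibrated gain.  Cached so several test files can share one fit.
canonical_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- make_benchmark(n_samples = 20, seed = 1)
      cache <<- list(bench = bench, fit = snn_fit(bench))
    }
    cache
  }
})
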