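test_that("parameter sets carry the printed constants", {
  ts <- izh_params("tonic")
  expect_identical(c(ts$a, ts$b, ts$c, ts$d), c(0.02, -0.1, -65, 6))
  iis <- izh_params("inhibition")
  expect_identical(c(iis$a, iis$b, iis$c, iis$d), c(-0.02, -1, -60, 8))
  expect_equal(izh_params("tonic", b = 0.2)$b, 0.2)
})

test_that("a single Euler step matches hand evaluation and applies the reset", {
  p <- izh_params("tonic")
  v <- -65; u <- p$b * v
  r <- izh_step(c(v, u), p, i_app = 0, dt = 0.1)
  expect_equal(unname(r$state[1]), v + 0.1 * (0.04 * v^2 + 5 * v + 140 - u))
  expect_equal(unname(r$state[2]), u + 0.1 * p$a * (p$b * v - u))
  expect_false(r$spiked)

  # a state just past threshold spikes and resets to (c, u + d)
  r2 <- izh_step(c(30.5, 0), p, i_app = 0, dt = 0.1)
  expect_true(r2$spiked)
  expect_equal(unname(r2$state[1]), p$c)
  expect_equal(unname(r2$state[2]),
               0 + 0.1 * p$a * (p$b * 30.5 - 0) + p$d)
})

test_that("invalid step inputs are rejected with diagnostics", {
  p <- izh_params("tonic")
  expect_error(izh_step(c(-65, 6.5), p, 0, dt = 0), "dt")
  expect_error(izh_step(c(NaN, 0), p, 0, dt = 0.1), "state")
  expect_error(izh_step(c(-65, 6.5), p, Inf, dt = 0.1), "i_app")
  expect_error(izh_simulate(p, 10, duration = -1), "duration")
})

test_that("negative current is clamped for tonic neurons only", {
  ts <- izh_params("tonic")
  expect_identical(izh_simulate(ts, -10, 300)$times,
                   izh_simulate(ts, 0, 300)$times)
  iis <- izh_params("inhibition")
  expect_false(identical(izh_simulate(iis, -40, 300)$times,
                         izh_simulate(iis, 0, 300)$times))
})

test_that("tonic firing increases with drive and IIS firing with inhibition", {
  fi <- neuron_fi("tonic", seq(0, 60, by = 5), duration = 500)
  expect_false(is.unsorted(fi$spikes))
  expect_gt(max(fi$spikes), 0)
  n_m20 <- length(izh_simulate(izh_params("inhibition"), -20, 500)$times)
  n_m5 <- length(izh_simulate(izh_params("inhibition"), -5, 500)$times)
  expect_gte(n_m20, n_m5)
  # complementarity: strong inhibition out-fires moderate excitation
  n_neg <- length(izh_simulate(izh_params("inhibition"), -80, 500)$times)
  n_pos <- length(izh_simulate(izh_params("inhibition"), 20, 500)$times)
  expect_gt(n_neg, n_pos)
})

test_that("every spike resets the state to v = c exactly", {
  for (kind in c("tonic", "inhibition")) {
    p <- izh_params(kind)
    i_app <- if (kind == "tonic") 40 else -60
    st <- c(p$c, p$b * p$c)
    for (k in 1:3000) {
      r <- izh_step(st, p, i_app, 0.1)
      if (r$spiked) expect_identical(unname(r$state[1]), p$c)
      st <- r$state
    }
  }
})

test_that("compiled and plain-R single-neuron paths agree exactly", {
  for (kind in c("tonic", "inhibition")) {
    p <- izh_params(kind)
    i_app <- if (kind == "tonic") 35 else -50
    st <- c(p$c, p$b * p$c)
    r_times <- numeric(0)
    for (k in 1:2000) {
      r <- izh_step(st, p, i_app, 0.1)
      if (r$spiked) r_times <- c(r_times, k * 0.1)
      st <- r$state
    }
    expect_identical(izh_simulate(p, i_app, 200, dt = 0.1)$times, r_times)
  }
})

test_that("halving the step moves the first spike by less than two steps", {
  for (I in c(30, 40, 60)) {
    t1 <- izh_simulate(izh_params("tonic"), I, 200, dt = 0.1)$times
    t2 <- izh_simulate(izh_params("tonic"), I, 200, dt = 0.05)$times
    expect_lt(abs(t1[1] - t2[1]), 2 * 0.1)
  }
})

test_that("spike counts are stable under step refinement", {
  for (I in c(40, 60)) {
    n1 <- length(izh_simulate(izh_params("tonic"), I, 500, dt = 0.1)$times)
    n2 <- length(izh_simulate(izh_params("tonic"), I, 500, dt = 0.01)$times)
    expect_lte(abs(n1 - n2) / n2, 0.05)
  }
})

test_that("spike trains validate their invariants", {
  expect_error(spike_train(c(3, 3), 10), "increasing")
  expect_error(spike_train(c(3, 11), 10), "within")
  st <- spike_train(c(3, 6), 10)
  expect_s3_class(st, "spike_train")
})
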