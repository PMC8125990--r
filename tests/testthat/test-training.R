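test_that("pattern averaging matches direct means and a loop oracle", {
  m <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(average_pattern(m), c(2, 2, 2))
  expect_equal(average_pattern(m, 1), c(1, 2, 3))
  set.seed(17)
  r <- matrix(runif(20), 5, 4)
  expect_equal(average_pattern(r), ref_column_means(r))
  expect_error(average_pattern(r, integer(0)), "no patterns")
})

test_that("the analytic weight rule reproduces the printed extremes", {
  expect_equal(compute_input_weights(26, 1.4, 26), 0)
  w <- compute_input_weights(6, 1.4, 26)
  expect_equal(w, 28)
  expect_gte(w, 8.08); expect_lte(w, 29.23)
  expect_equal(compute_input_weights(65.79, 1.4, 26), -55.706)
})

test_that("neuron mapping follows the weight sign with zero going tonic", {
  expect_identical(map_neurons(c(-1, 0, 1)),
                   c("inhibition", "tonic", "tonic"))
  set.seed(18)
  w <- rnorm(100)
  expect_identical(map_neurons(w) == "inhibition", w < 0)
})

test_that("suggested learning parameters anchor at N = 20 and stay in range", {
  s20 <- suggest_delta_kappa(20)
  expect_equal(s20$delta, 1.4)
  expect_equal(s20$kappa, 26)
  s40 <- suggest_delta_kappa(40)
  expect_lte(s40$delta, 1.4)
  expect_gte(s40$kappa, 26)
  for (n in 10:40) {
    s <- suggest_delta_kappa(n)
    expect_gte(s$delta, 0.95); expect_lte(s$delta, 1.4)
    expect_gte(s$kappa, 26); expect_lte(s$kappa, 32)
  }
  expect_warning(suggest_delta_kappa(8), "extrapolating")
})

test_that("identical training patterns give a zero threshold and modal responses", {
  set.seed(19)
  pars <- fusion_params(15, noise_sd = 0)
  one <- make_positive(pars, 1)$patterns
  m <- one[rep(1, 8), ]
  fit <- snn_fit(m, rep(TRUE, 8))
  expect_equal(fit$se_threshold, 0)
  expect_true(all(fit$training$se == 0))
  expect_equal(unname(unlist(fit$training[1, c("dt1", "dt2")])),
               fit$code_mode)
})

test_that("refitting the same seeded benchmark reproduces the model exactly", {
  b1 <- make_benchmark(20, seed = 3)
  b2 <- make_benchmark(20, seed = 3)
  expect_identical(b1$patterns, b2$patterns)
  f1 <- snn_fit(b1)
  f2 <- snn_fit(b2)
  f1$training <- f2$training <- NULL
  expect_identical(unclass(f1), unclass(f2))
})

test_that("only the input weights are data-dependent in the fitted model", {
  cf <- canonical_fit()
  fit <- cf$fit
  expect_length(fit$w1, 20)
  expect_identical(fit$w2, 0.0025)
  expect_identical(fit$c_ref, 0.0083)
  expect_identical(fit$neuron_map, map_neurons(fit$w1))
  # the mapping is the analytic rule applied to the positive average
  avg <- average_pattern(pmax(cf$bench$patterns, 0),
                         which(cf$bench$labels))
  expect_equal(fit$w1, compute_input_weights(avg, fit$delta, fit$kappa))
})

test_that("the strict all-pattern averaging switch changes the reference", {
  cf <- canonical_fit()
  fit_all <- snn_fit(cf$bench, average_all = TRUE)
  avg_all <- average_pattern(pmax(cf$bench$patterns, 0))
  expect_equal(fit_all$w1,
               compute_input_weights(avg_all, fit_all$delta, fit_all$kappa))
  expect_false(isTRUE(all.equal(fit_all$w1, cf$fit$w1)))
})

test_that("fit fails with a calibration diagnostic when positives cannot respond", {
  set.seed(20)
  pars <- fusion_params(10)
  m <- make_positive(pars, 5)$patterns
  expect_error(snn_fit(m, rep(TRUE, 5), input_gain = 1e-6),
               "fewer than 2 output spikes")
})

test_that("methods expose the fitted model coherently", {
  cf <- canonical_fit()
  fit <- cf$fit
  expect_output(print(fit), "response mode")
  sm <- summary(fit)
  expect_equal(sm$accuracy, accuracy(sm$confusion))
  expect_equal(unname(coef(fit)[["w2"]]), 0.0025)
  expect_length(residuals(fit), 80)
  pr <- predict(fit, cf$bench$patterns[1:5, ], type = "response")
  expect_identical(nrow(pr), 5L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
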