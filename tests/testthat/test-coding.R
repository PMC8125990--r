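test_that("latency extraction reads onset latency then interspike intervals", {
  expect_equal(extract_latencies(spike_train(c(3, 6), 100)), c(3, 3))
  expect_equal(extract_latencies(spike_train(c(4, 10), 100)), c(4, 6))
  one <- spike_train(5, 100)
  expect_equal(extract_latencies(one, k = 1), 5)
  expect_null(extract_latencies(one, k = 2))
  # quantization rounds half up on the bin grid
  expect_equal(extract_latencies(spike_train(c(2.5, 5.9), 100)), c(3, 3))
})

test_that("squared error reproduces the worked response-table values", {
  mode <- c(3, 3)
  cases <- list(list(c(3, 3), 0), list(c(4, 5), 5), list(c(4, 6), 10),
                list(c(5, 7), 20), list(c(8, 4), 26), list(c(8, 5), 29),
                list(c(9, 4), 37), list(c(18, 15), 369), list(c(19, 15), 400),
                list(c(25, 13), 584), list(c(27, 8), 601))
  for (cs in cases) expect_identical(squared_error(cs[[1]], mode), cs[[2]])
})

test_that("squared error matches a brute-force loop on random pairs", {
  set.seed(12)
  for (i in 1:10000) {
    code <- sample(0:40, 2, replace = TRUE)
    mode <- sample(0:40, 2, replace = TRUE)
    expect_identical(squared_error(code, mode), ref_squared_error(code, mode))
  }
})

test_that("mean squared error averages, permutes freely, and rejects empties", {
  expect_equal(latency_mse(list(c(5, 7)), c(3, 3)), 20)
  expect_equal(latency_mse(list(c(3, 3), c(5, 7)), c(3, 3)), 10)
  set.seed(13)
  codes <- replicate(6, sample(0:20, 2), simplify = FALSE)
  expect_equal(latency_mse(codes, c(3, 3)),
               latency_mse(rev(codes), c(3, 3)))
  expect_error(latency_mse(list(), c(3, 3)), "non-empty")
})

test_that("threshold classification accepts ties and rejects no-responses", {
  expect_true(classify_se(10, 10))
  expect_false(classify_se(20, 10))
  expect_false(classify_se(NA_real_, 10))
  expect_identical(classify_se(c(0, 10, 11, NA), 10),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("accuracy reproduces the worked confusion rows and its bounds", {
  expect_equal(accuracy(list(tp = 40, tn = 38, fp = 2, fn = 0)), 0.975)
  expect_equal(accuracy(list(tp = 40, tn = 37, fp = 3, fn = 0)), 0.9625)
  expect_equal(accuracy(list(tp = 40, tn = 40, fp = 0, fn = 0)), 1)
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
  set.seed(14)
  for (i in 1:200) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cc)) == 0) next
    a <- accuracy(cc)
    expect_gte(a, 0)
    expect_lte(a, 1)
    expect_identical(a == 1, cc$fp == 0 && cc$fn == 0)
  }
})

test_that("raising the threshold never loses positives nor gains negatives", {
  set.seed(15)
  se <- c(sample(0:50, 40, replace = TRUE), NA)
  truth <- c(rep(TRUE, 20), rep(FALSE, 21))
  prev_tp <- -1; prev_tn <- Inf
  for (thr in seq(0, 60, by = 5)) {
    cc <- confusion_counts(classify_se(se, thr), truth)
    expect_gte(cc$tp, prev_tp)
    expect_lte(cc$tn, prev_tn)
    prev_tp <- cc$tp; prev_tn <- cc$tn
  }
})

test_that("max sampling frequency is the reciprocal of summed worst latencies", {
  expect_equal(max_sampling_frequency(list(c(3, 3), c(4, 5), c(4, 6))), 100)
  expect_equal(max_sampling_frequency(list(c(10, 10))), 50)
  # adding a dominated code changes nothing
  expect_equal(max_sampling_frequency(list(c(4, 6), c(2, 2))),
               max_sampling_frequency(list(c(4, 6))))
  expect_error(max_sampling_frequency(list()), "non-empty")
})

test_that("the first-spike baseline drops exactly the second SE component", {
  set.seed(16)
  mode <- c(3, 3)
  for (i in 1:50) {
    code <- sample(0:20, 2)
    expect_equal(squared_error(code, mode) - (code[1] - mode[1])^2,
                 (code[2] - mode[2])^2)
  }
  # equivalent to the two-latency rule when all second latencies coincide
  dt1 <- c(3, 4, 9, NA)
  two <- classify_se(c(0, 1, 36, NA) , 1)  # codes (3,3),(4,3),(9,3) vs (3,3)
  one <- first_spike_classify(dt1, 3, 1)
  expect_identical(two, one)
})
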