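test_that("moving average follows the truncated-window arithmetic", {
  expect_equal(moving_average(rep(3.3, 7), 5), rep(3.3, 7))
  expect_equal(moving_average(c(0, 0, 1, 0, 0), 3), c(0, 1/3, 1/3, 1/3, 0))
  expect_error(moving_average(numeric(0), 3), "empty")
  expect_error(moving_average(1:5, 9), "window_points")

  withr::local_seed(5)
  x <- rnorm(1e4)
  got <- moving_average(x, 100)
  # brute-force windowed mean with the same centering convention
  hl <- 49L; hr <- 50L
  brute <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - hl):min(length(x), i + hr)])
  }, numeric(1))
  expect_lt(max(abs(got - brute)), 1e-12)
  expect_length(got, length(x))
})

test_that("ratio computation guards the denominator", {
  expect_equal(compute_ratio(c(1, 2, 3), c(1, 2, 3)), c(1, 1, 1))
  expect_equal(compute_ratio(c(2, 4), c(1, 2)), c(2, 2))
  expect_error(compute_ratio(c(1, 2), c(1, 0)), "index 2")
  expect_error(compute_ratio(1:3, 1:2), "equal length")
})

test_that("baseline normalization satisfies its algebraic identities", {
  tr <- tibble::tibble(time = seq(0, 20, by = 0.1), value = 2)
  d <- normalize_trace(tr, anchor_time = 10, baseline_dur = 5, mode = "delta")
  expect_true(all(d$value == 0))
  p <- normalize_trace(tr, anchor_time = 10, baseline_dur = 5, mode = "percent")
  expect_true(all(p$value == 100))

  tr2 <- tibble::tibble(time = seq(0, 20, by = 0.1),
                        value = c(rep(2, 100), rep(2.2, 101)))
  d2 <- normalize_trace(tr2, anchor_time = 10, baseline_dur = 5)
  expect_equal(d2$value[d2$time > 0][1], 0.1, tolerance = 1e-12)

  # mean over the baseline window is exactly zero for any input
  withr::local_seed(8)
  for (i in 1:10) {
    trr <- tibble::tibble(time = seq(0, 30, by = 0.05),
                          value = abs(rnorm(601)) + 0.5)
    dn <- normalize_trace(trr, anchor_time = 12, baseline_dur = 5)
    expect_lt(abs(mean(dn$value[dn$time >= -5 & dn$time < 0])), 1e-12)
  }
  expect_error(normalize_trace(tr, anchor_time = 2, baseline_dur = 5),
               "before the start")
})

test_that("windowed AUC handles exclusions and matches a Riemann oracle", {
  rate <- 100
  tt <- seq(-10, 40, by = 1 / rate)
  zero <- tibble::tibble(time = tt, value = 0)
  expect_equal(windowed_auc(zero), 0)

  const <- tibble::tibble(time = tt, value = 0.01)
  expect_equal(windowed_auc(const), 0.29, tolerance = 1e-12)

  withr::local_seed(9)
  for (i in 1:20) {
    tr <- tibble::tibble(time = tt, value = cumsum(rnorm(length(tt), 0, 0.01)))
    got <- windowed_auc(tr, c(0, 30), list(c(0, 1), c(30, 31)))
    want <- riemann_auc_oracle(tr, c(0, 30), list(c(0, 1), c(30, 31)))
    expect_lt(abs(got - want), 1e-9 * max(1, abs(want)))
  }
  expect_error(windowed_auc(const, c(0, 30), list(c(0, 30))), "whole window")
})

test_that("AUC is linear in the trace", {
  tt <- seq(-5, 35, by = 0.02)
  withr::local_seed(10)
  x <- tibble::tibble(time = tt, value = rnorm(length(tt)))
  y <- tibble::tibble(time = tt, value = rnorm(length(tt)))
  mix <- tibble::tibble(time = tt, value = 2 * x$value - 3 * y$value)
  expect_equal(windowed_auc(mix),
               2 * windowed_auc(x) - 3 * windowed_auc(y),
               tolerance = 1e-9)
})

test_that("signed AUC split is additive and sign-correct", {
  tt <- seq(0, 1, by = 1e-3)
  sine <- tibble::tibble(time = tt, value = sin(2 * pi * tt))
  s <- split_signed_auc(sine, c(0, 1))
  expect_equal(s$auc_positive, -s$auc_negative, tolerance = 1e-9)
  expect_lt(abs(s$auc_total), 1e-9)

  pos <- tibble::tibble(time = tt, value = abs(sin(2 * pi * tt)))
  expect_equal(split_signed_auc(pos, c(0, 1))$auc_negative, 0)

  withr::local_seed(11)
  arb <- tibble::tibble(time = tt, value = rnorm(length(tt)))
  sa <- split_signed_auc(arb, c(0, 1))
  expect_equal(sa$auc_positive + sa$auc_negative, sa$auc_total,
               tolerance = 1e-9)
})

test_that("extrema search covers peaks, troughs and degenerate traces", {
  tt <- seq(0, 30, by = 0.01)
  tri <- tibble::tibble(time = tt, value = pmax(0, 1 - abs(tt - 10) / 5))
  ext <- find_extrema(tri, c(0, 30), mode = "peak")
  expect_equal(ext$peak_time, 10)
  expect_equal(ext$peak_value, 1)

  expect_warning(
    ext2 <- find_extrema(tibble::tibble(time = tt, value = 1), c(0, 30),
                         mode = "trough"),
    "flat"
  )
  expect_equal(ext2$trough_time, 0)

  pos_pulse <- tibble::tibble(time = tt, value = exp(-(tt - 10)^2))
  ext3 <- find_extrema(pos_pulse, c(5, 30), mode = "trough")
  expect_true(ext3$trough_time %in% c(5, 30)) # boundary trough
})

test_that("biphasic extrema match the analytic kernel within 2 s", {
  rate <- 100
  tt <- seq(0, 120, by = 1 / rate)
  kern <- response_kernel(tt, 0.01, 25, 10, 60) -
    response_kernel(tt, 0.008, 0.5, 1.5, 8)
  tr <- tibble::tibble(time = tt, value = kern)
  ext <- find_extrema(tr, c(0, 120), mode = "biphasic")
  # independent oracle: extrema of the kernel on a 10x finer grid
  tf <- seq(0, 120, by = 1 / (10 * rate))
  kf <- response_kernel(tf, 0.01, 25, 10, 60) -
    response_kernel(tf, 0.008, 0.5, 1.5, 8)
  expect_lt(abs(ext$trough_time - tf[which.min(kf)]), 2)
  expect_lt(abs(ext$peak_time - tf[which.max(kf)]), 2)
  expect_lt(ext$trough_time, ext$peak_time)
})

test_that("response kernel peaks at its analytic peak time", {
  tt <- seq(0, 300, by = 0.001)
  k <- response_kernel(tt, 2, 1, 5, 40)
  expect_equal(tt[which.max(k)], kernel_peak_time(1, 5, 40), tolerance = 0.01)
  expect_equal(max(k), 2, tolerance = 1e-6)
})
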