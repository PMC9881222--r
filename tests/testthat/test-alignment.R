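flat_trace <- function(duration = 600, rate = 100, value = 1) {
  tibble::tibble(time = seq(0, duration - 1 / rate, by = 1 / rate),
                 value = value)
}

test_that("out-of-bounds events are skipped and counted like a brute scan", {
  tr <- flat_trace(200)
  expect_message(
    ens <- extract_snippets(tr, c(2, 50, 100, 195), pre = 5, post = 20,
                            baseline_dur = 5),
    "skipped"
  )
  onsets <- c(2, 50, 100, 195)
  brute <- sum(onsets - 5 >= 0 & onsets + 20 <= max(tr$time))
  expect_equal(ens$n_events, brute)

  withr::local_seed(12)
  for (i in 1:10) {
    on <- sort(runif(12, -10, 220))
    got <- tryCatch(
      suppressMessages(
        extract_snippets(tr, on, pre = 5, post = 20, baseline_dur = 5)
      )$n_events,
      error = function(e) 0
    )
    expect_equal(got, sum(on - 5 >= 0 & on + 20 <= max(tr$time)))
  }
})

test_that("identical injected responses average to themselves", {
  rate <- 100
  tr <- flat_trace(400, rate)
  kern <- response_kernel(seq(0, 100, by = 1 / rate), 0.01, 1, 5, 40)
  for (on in c(100, 250)) {
    idx <- round(on * rate):(round(on * rate) + length(kern) - 1)
    tr$value[idx] <- tr$value[idx] * (1 + kern)
  }
  ens <- extract_snippets(tr, c(100, 250), pre = 10, post = 90)
  expect_equal(ens$n_events, 2)
  expect_lt(max(abs(ens$snippets[1, ] - ens$snippets[2, ])), 1e-12)
  ses <- session_average(ens)
  expect_lt(max(abs(ses$trace$mean - ens$snippets[1, ])), 1e-12)
})

test_that("session validity follows the study rules", {
  tr <- flat_trace(900)
  two <- extract_snippets(tr, c(100, 500), pre = 10, post = 120)
  s2 <- session_average(two, design = "stim")
  expect_false(s2$valid)
  expect_equal(s2$reason, "n_events<3")

  three <- extract_snippets(tr, c(100, 400, 700), pre = 10, post = 120)
  expect_true(session_average(three, design = "stim")$valid)
  # strict "more than 3" reading by config
  expect_false(session_average(three, design = "stim", min_events = 4)$valid)

  one <- extract_snippets(tr, 400, pre = 30, post = 60)
  expect_true(session_average(one, design = "transition")$valid)
})

test_that("group averages report SEM and count only valid sessions", {
  tr <- flat_trace(900)
  mk <- function(val, n_ev) {
    tr2 <- tr; tr2$value <- val
    ons <- seq(100, by = 150, length.out = n_ev)
    session_average(extract_snippets(tr2, ons, pre = 10, post = 120,
                                     mode = "shift"),
                    design = "stim", session_id = paste0("s", val))
  }
  sessions <- list(mk(1, 3), mk(2, 3), mk(3, 3), mk(9, 2))
  g <- group_average(sessions)
  expect_equal(g$n_sessions, 3)
  expect_equal(g$n_excluded, 1)
  expect_true(all(g$trace$n == 3))

  # SEM equals sd/sqrt(n) recomputed by brute force at random time points
  m <- vapply(sessions[1:3], function(s) s$trace$mean,
              numeric(nrow(sessions[[1]]$trace)))
  withr::local_seed(13)
  for (i in sample(nrow(m), 20)) {
    expect_equal(g$trace$sem[i], sd(m[i, ]) / sqrt(3), tolerance = 1e-12)
  }

  same <- list(mk(4, 3), mk(4, 3))
  expect_true(all(group_average(same)$trace$sem == 0))
  expect_error(group_average(list(mk(1, 3), mk(2, 2))), "2 valid sessions")
})

test_that("mean of session means equals the grand mean for equal n", {
  rate <- 50
  tr <- flat_trace(2000, rate)
  withr::local_seed(14)
  tr$value <- 1 + cumsum(rnorm(nrow(tr), 0, 1e-4))
  ons1 <- c(200, 500, 800)
  ons2 <- c(1100, 1400, 1700)
  e1 <- extract_snippets(tr, ons1, pre = 10, post = 60)
  e2 <- extract_snippets(tr, ons2, pre = 10, post = 60)
  g <- group_average(list(session_average(e1), session_average(e2)))
  all6 <- extract_snippets(tr, c(ons1, ons2), pre = 10, post = 60)
  expect_lt(max(abs(g$trace$mean - colMeans(all6$snippets))), 1e-12)
})

test_that("averaging suppresses noise as 1/sqrt(n events)", {
  rate <- 50
  withr::local_seed(15)
  base <- flat_trace(4000, rate)
  kern <- response_kernel(seq(0, 80, by = 1 / rate), 0.02, 1, 5, 40)
  rmse_for <- function(n_ev) {
    tr <- base
    tr$value <- 1 + rnorm(nrow(tr), 0, 0.005)
    ons <- seq(100, by = 90, length.out = n_ev)
    for (on in ons) {
      idx <- round(on * rate):(round(on * rate) + length(kern) - 1)
      tr$value[idx] <- tr$value[idx] + kern
    }
    ens <- extract_snippets(tr, ons, pre = 5, post = 80, mode = "shift")
    m <- colMeans(ens$snippets)
    want <- c(rep(0, 5 * rate), kern)[seq_along(m)]
    sqrt(mean((m - want)^2))
  }
  r4 <- rmse_for(4)
  r36 <- rmse_for(36)
  expect_lt(r36, r4 / 1.8) # expected factor 3, generous margin
})

test_that("condition pairing aligns by key and reports unpaired rows", {
  tab <- tibble::tibble(
    session_id = rep(paste0("m", 1:5), 2),
    condition = rep(c("Pre", "Drug"), each = 5),
    auc = 1:10
  )
  pr <- pair_conditions(tab, "Pre", "Drug")
  expect_equal(pr$a, 1:5)
  expect_equal(pr$b, 6:10)

  tab2 <- tab[-8, ]
  expect_warning(pr2 <- pair_conditions(tab2, "Pre", "Drug"), "m3")
  expect_length(pr2$a, 4)

  # order invariance
  withr::local_seed(16)
  tab3 <- tab[sample(nrow(tab)), ]
  pr3 <- pair_conditions(tab3, "Pre", "Drug")
  expect_equal(pr3$a, pr$a)
  expect_equal(pr3$b, pr$b)

  expect_error(pair_conditions(tab[1:5, ], "Pre", "Drug"), "zero complete")
})
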