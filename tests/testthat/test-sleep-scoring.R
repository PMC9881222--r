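test_that("epoch features capture narrowband and flat spectra", {
  rate <- 200
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  sine <- sin(2 * pi * 2 * t)
  f <- epoch_features(sine, numeric(length(t)), rate)
  expect_true(all(f$delta_power / f$total_power > 0.9))
  expect_true(all(f$emg_rms == 0))

  withr::local_seed(1)
  wn <- rnorm(length(t))
  fw <- epoch_features(wn, wn, rate)
  frac <- sum(fw$delta_power) / sum(fw$total_power)
  expect_lt(abs(frac - 3.5 / 100) / (3.5 / 100), 0.2)
})

test_that("too-short epochs and partial epochs are handled", {
  rate <- 200
  x <- rnorm(rate * 10)
  expect_error(epoch_features(x, x, rate, epoch_len = 2), "2 cycles")
  expect_warning(epoch_features(x[1:(rate * 9.5)], x[1:(rate * 9.5)], rate),
                 "partial epoch")
})

test_that("classification follows the EMG-then-theta/delta rule tree", {
  feats <- tibble::tibble(
    epoch = 1:4, t_start = (0:3) * 4,
    delta_power = c(10, 10, 1, 1),
    theta_power = c(1, 1, 10, 10),
    total_power = 20,
    emg_rms = c(5, 0.1, 0.1, 5)
  )
  hyp <- classify_epochs(feats, score_thresholds(emg = 1), epoch_len = 4)
  expect_equal(hyp$epochs$state, c("wake", "nrem", "rem", "wake"))
  expect_equal(hyp$seconds$state[1:8], c(rep("wake", 4), rep("nrem", 4)))
})

test_that("non-finite features flag the epoch and inherit the previous label", {
  feats <- tibble::tibble(
    epoch = 1:3, t_start = (0:2) * 4,
    delta_power = c(10, NA, 10), theta_power = 1, total_power = 12,
    emg_rms = c(0.1, 0.1, 0.1)
  )
  hyp <- classify_epochs(feats, score_thresholds(emg = 1))
  expect_equal(hyp$epochs$state, c("nrem", "nrem", "nrem"))
  expect_equal(hyp$epochs$unscorable, c(FALSE, TRUE, FALSE))
})

test_that("smoothing removes isolated single REM epochs inside wake", {
  feats <- tibble::tibble(
    epoch = 1:3, t_start = (0:2) * 4,
    delta_power = c(1, 1, 1), theta_power = c(0.1, 10, 0.1),
    total_power = 12, emg_rms = c(5, 0.1, 5)
  )
  hyp <- classify_epochs(feats, score_thresholds(emg = 1, smooth = TRUE))
  expect_equal(hyp$epochs$state, c("wake", "wake", "wake"))
  hyp2 <- classify_epochs(feats, score_thresholds(emg = 1, smooth = FALSE))
  expect_equal(hyp2$epochs$state, c("wake", "rem", "wake"))
})

test_that("second-level refinement moves wake onsets to the EMG crossing", {
  feats <- tibble::tibble(
    epoch = 1:2, t_start = c(0, 4),
    delta_power = c(10, 1), theta_power = c(1, 1), total_power = 12,
    emg_rms = c(0.1, 5)
  )
  hyp <- classify_epochs(feats, score_thresholds(emg = 1))
  plain <- refine_to_seconds(hyp)
  expect_equal(plain$state, c(rep("nrem", 4), rep("wake", 4)))
  # EMG crosses the threshold 2 s into the NREM epoch preceding wake
  emg_sec <- c(0.1, 0.1, 5, 5, 5, 5, 5, 5)
  ref <- refine_to_seconds(hyp, emg_sec = emg_sec, refine = TRUE, emg_thr = 1)
  expect_equal(ref$state, c(rep("nrem", 2), rep("wake", 6)))
  # single-state hypnograms are unchanged by refinement
  feats1 <- dplyr::mutate(feats, emg_rms = c(5, 5))
  hyp1 <- classify_epochs(feats1, score_thresholds(emg = 1))
  expect_equal(refine_to_seconds(hyp1, emg_sec = emg_sec, refine = TRUE,
                                 emg_thr = 1)$state,
               rep("wake", 8))
})

test_that("transition detection matches the rules and a brute-force scan", {
  secs <- tibble::tibble(time = 0:99,
                         state = c(rep("nrem", 60), rep("wake", 40)))
  tr <- detect_transitions(secs, "nrem", "wake", min_bout_after = 30)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$time, 60)
  expect_equal(tr$bout_duration_after, 40)

  short <- tibble::tibble(time = 0:89,
                          state = c(rep("nrem", 60), rep("wake", 20),
                                    rep("nrem", 10)))
  expect_equal(nrow(detect_transitions(short, "nrem", "wake", 30)), 0)

  ev <- detect_transitions(
    tibble::tibble(time = 0:99, state = c(rep("nrem", 58), rep("wake", 42))),
    "nrem", "wake", min_bout_after = 30, stim_onsets = 55
  )
  expect_equal(ev$origin, "evoked")

  # oracle equivalence on random label strings
  withr::local_seed(42)
  for (i in 1:20) {
    labs <- sample(c("wake", "nrem", "rem"), 300, replace = TRUE)
    secs <- tibble::tibble(time = 0:299, state = labs)
    got <- detect_transitions(secs, "nrem", "wake", 0)$time
    brute <- which(labs[-1] == "wake" & labs[-300] == "nrem")
    expect_equal(got, brute)
  }
})

test_that("sub-state onset detection finds bursts and nothing else", {
  rate <- 200
  n_sec <- 300
  withr::local_seed(7)
  emg <- rnorm(n_sec * rate, 0, 1)
  burst <- 120
  emg[(burst * rate + 1):((burst + 2) * rate)] <-
    emg[(burst * rate + 1):((burst + 2) * rate)] * 10
  secs <- tibble::tibble(time = 0:(n_sec - 1), state = "nrem")
  det <- detect_substate_onsets(emg, rate, secs, "nrem", k = 10)
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$time - burst), 1)
  expect_equal(det$kind, "micro_awakening")
  # the threshold equals mean + k*SD of the within-state metric
  m <- emg_rms_per_second(emg, rate)
  expect_equal(det$threshold, mean(m) + 10 * sd(m))
  # the k*SD-only reading is one flag away
  det2 <- detect_substate_onsets(emg, rate, secs, "nrem", k = 10,
                                 rule = "k_sd")
  expect_equal(det2$threshold[1], 10 * sd(m))

  # burst-free trace: zero onsets at k = 10
  emg0 <- rnorm(n_sec * rate, 0, 1)
  expect_equal(nrow(detect_substate_onsets(emg0, rate, secs, "nrem")), 0)
  expect_error(
    detect_substate_onsets(emg, rate, secs[1:30, ], "nrem"),
    "60 s"
  )
})

test_that("scoring a default synthetic recording recovers the hypnogram", {
  cfg <- test_config(seed = 31, duration = 3600)
  rec <- simulate_recording(cfg, with_eeg = TRUE)
  gt <- attr(rec, "ground_truth")
  hyp <- score_sleep(rec)
  truth <- sleepfp:::truth_epoch_labels(gt$hypnogram$seconds, 4)
  acc <- mean(hyp$epochs$state == truth[seq_len(nrow(hyp$epochs))])
  expect_gte(acc, 0.95)
})
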