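#' Per-epoch EEG/EMG features
#'
#' For each non-overlapping epoch (default 4 s): delta (0.5-4 Hz) and theta
#' (6-9 Hz) band powers and total power from a Hann-windowed periodogram of
#' the epoch (Welch estimate with segment length equal to the epoch), plus
#' the RMS of the 10-100 Hz band-passed EMG. A trailing partial epoch is
#' dropped with a warning. The epoch must contain at least two cycles of the
#' lowest delta frequency (i.e. `epoch_len >= 4` s for a 0.5-Hz band edge).
#'
#' @param eeg,emg Numeric vectors covering the same duration.
#' @param rate Sampling rate in Hz (shared).
#' @param epoch_len Epoch length in seconds.
#' @param delta,theta Band limits in Hz.
#' @return Tibble with one row per epoch: `epoch`, `t_start`,
#'   `delta_power`, `theta_power`, `total_power`, `emg_rms`.
#' @export
epoch_features <- function(eeg, emg, rate, epoch_len = 4,
                           delta = c(0.5, 4), theta = c(6, 9)) {
  if (abs(length(eeg) - length(emg)) > rate * epoch_len) {
    abort("eeg and emg must cover the same duration")
  }
  if (epoch_len * delta[1] < 2) {
    abort("epoch shorter than 2 cycles of the lowest delta frequency")
  }
  spp <- round(epoch_len * rate)
  n_ep <- floor(min(length(eeg), length(emg)) / spp)
  if (n_ep < 1) abort("no complete epoch in the input")
  if (n_ep * spp < length(eeg)) {
    warn("trailing partial epoch dropped")
  }

  emg_f <- band_filter(emg, rate, c(10, 100))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, spp - 1) / (spp - 1))
  freqs <- (seq_len(spp) - 1L) / spp * rate
  half <- freqs > 0 & freqs <= rate / 2
  in_delta <- half & freqs >= delta[1] & freqs <= delta[2]
  in_theta <- half & freqs >= theta[1] & freqs <= theta[2]

  res <- purrr::map_dfr(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * spp + 1L):(i * spp)
    seg <- eeg[idx] * hann
    pw <- Mod(fft(seg))^2
    tibble(
      epoch = i, t_start = (i - 1) * epoch_len,
      delta_power = sum(pw[in_delta]),
      theta_power = sum(pw[in_theta]),
      total_power = sum(pw[half]),
      emg_rms = sqrt(mean(emg_f[idx]^2))
    )
  })
  res
}

# zero-phase FFT band-pass (upper edge capped below Nyquist)
band_filter <- function(x, rate, band) {
  n <- length(x)
  hi <- min(band[2], 0.45 * rate)
  xf <- fft(x)
  f <- (seq_len(n) - 1L) / n * rate
  f <- pmin(f, rate - f)
  xf[f < band[1] | f > hi] <- 0 + 0i
  Re(fft(xf, inverse = TRUE)) / n
}

#' Scoring thresholds
#'
#' @param emg EMG RMS wake threshold, or `"auto"`: a deterministic 2-class
#'   (Otsu) split of the log epoch EMG RMS, which assumes both wake and
#'   sleep are present in the recording.
#' @param theta_delta Theta/delta power ratio above which a low-EMG epoch is
#'   REM.
#' @param smooth Forbid isolated single REM epochs inside wake.
#' @return List of thresholds for [classify_epochs()].
#' @export
score_thresholds <- function(emg = "auto", theta_delta = 1, smooth = TRUE) {
  list(emg = emg, theta_delta = theta_delta, smooth = smooth)
}

# deterministic Otsu threshold on a numeric vector
otsu_threshold <- function(v) {
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  between <- k * (n - k) * (m1 - m2)^2
  kbest <- which.max(between)
  (vs[kbest] + vs[kbest + 1]) / 2
}

#' Classify epochs into wake / NREM / REM
#'
#' The conventional EMG-then-theta/delta decision tree standing in for
#' standard visual scoring criteria: an epoch with EMG RMS above the wake
#' threshold is wake; otherwise theta/delta above `theta_delta` makes it
#' REM, else NREM. Optional smoothing relabels isolated single REM epochs
#' flanked by wake. Epochs with non-finite features are flagged unscorable
#' and inherit the previous epoch's label.
#'
#' @param features From [epoch_features()].
#' @param thresholds From [score_thresholds()].
#' @param epoch_len Epoch length in seconds.
#' @return An object of class `fp_hypnogram`: list with `epochs` (features
#'   plus `state`, `unscorable`), `seconds` (tibble `time`, `state`),
#'   `epoch_len` and the thresholds used.
#' @export
classify_epochs <- function(features, thresholds = score_thresholds(),
                            epoch_len = 4) {
  emg_thr <- thresholds$emg
  if (identical(emg_thr, "auto")) {
    emg_thr <- exp(otsu_threshold(log(features$emg_rms + 1e-12)))
  }
  ratio <- features$theta_power / features$delta_power
  ok <- is.finite(features$emg_rms) & is.finite(ratio)
  state <- ifelse(features$emg_rms > emg_thr, "wake",
                  ifelse(ratio > thresholds$theta_delta, "rem", "nrem"))
  state[!ok] <- NA
  # unscorable epochs inherit the previous label (first epoch falls to nrem)
  for (i in seq_along(state)) {
    if (is.na(state[i])) state[i] <- if (i > 1) state[i - 1] else "nrem"
  }
  if (isTRUE(thresholds$smooth) && length(state) >= 3) {
    iso <- which(state == "rem" &
                   dplyr::lag(state) == "wake" & dplyr::lead(state) == "wake")
    state[iso] <- "wake"
  }
  epochs <- mutate(features, state = state, unscorable = !ok)
  structure(
    list(
      epochs = epochs,
      seconds = tibble(
        time = seq_len(nrow(epochs) * epoch_len) - 1L,
        state = rep(state, each = epoch_len)
      ),
      epoch_len = epoch_len,
      thresholds = list(emg = emg_thr, theta_delta = thresholds$theta_delta)
    ),
    class = "fp_hypnogram"
  )
}

#' Refine epoch labels to 1-s labels
#'
#' Expands each scored epoch into `epoch_len` identical 1-s labels (the
#' virtual rescoring of 4-s scores to every second). With `refine = TRUE`
#' and a per-second EMG metric, a wake onset is additionally moved earlier
#' within the preceding epoch to the first second whose EMG crosses the wake
#' threshold, so state boundaries can shift by at most one epoch and the
#' multiset of states present never changes.
#'
#' @param hypnogram An `fp_hypnogram`.
#' @param emg_sec Optional per-second EMG RMS vector (for refinement).
#' @param refine Apply EMG boundary refinement at wake onsets.
#' @param emg_thr Wake threshold; defaults to the one stored in the
#'   hypnogram.
#' @return Tibble `time`, `state` with one row per second.
#' @export
refine_to_seconds <- function(hypnogram, emg_sec = NULL, refine = FALSE,
                              emg_thr = NULL) {
  secs <- hypnogram$seconds
  if (!refine) return(secs)
  if (is.null(emg_sec)) abort("refinement needs a per-second EMG metric")
  emg_thr <- emg_thr %||% hypnogram$thresholds$emg
  el <- hypnogram$epoch_len
  st <- hypnogram$epochs$state
  out <- secs$state
  wake_onsets <- which(st == "wake" & dplyr::lag(st) != "wake")
  for (i in wake_onsets) {
    prev_sec <- ((i - 2L) * el + 1L):((i - 1L) * el) # seconds of epoch i-1
    prev_sec <- prev_sec[prev_sec >= 1 & prev_sec <= length(emg_sec)]
    cross <- prev_sec[emg_sec[prev_sec] > emg_thr]
    if (length(cross) > 0) out[min(cross):((i - 1L) * el)] <- "wake"
  }
  tibble(time = secs$time, state = out)
}

#' Per-second EMG RMS metric
#'
#' @param emg Raw EMG vector.
#' @param rate Sampling rate (Hz).
#' @return Numeric vector, one RMS value per whole second of band-passed
#'   (10-100 Hz) EMG.
#' @export
emg_rms_per_second <- function(emg, rate) {
  emg_f <- band_filter(emg, rate, c(10, 100))
  n_sec <- floor(length(emg) / rate)
  vapply(seq_len(n_sec), function(s) {
    sqrt(mean(emg_f[((s - 1) * rate + 1):(s * rate)]^2))
  }, numeric(1))
}

#' Detect state transitions in 1-s labels
#'
#' A transition happens at second `t` when the label switches from
#' `from_state` to `to_state` and the new state persists at least
#' `min_bout_after` seconds (30 s for the spontaneous-awakening analysis of
#' NREM-to-wake transitions, 0 otherwise). When stimulation onsets are
#' given, a transition with a stimulation in `[t - 35, t]` is flagged
#' `evoked`, otherwise `spontaneous`.
#'
#' @param seconds Tibble `time`, `state` at 1-s resolution.
#' @param from_state,to_state State labels.
#' @param min_bout_after Minimum duration of the new state in seconds.
#' @param stim_onsets Numeric vector of stimulation onset times (or `NULL`).
#' @return Tibble `time`, `from_state`, `to_state`, `bout_duration_after`,
#'   `origin`.
#' @export
detect_transitions <- function(seconds, from_state, to_state,
                               min_bout_after = 0, stim_onsets = NULL) {
  bouts <- labels_to_bouts(seconds$state, t0 = min(seconds$time))
  idx <- which(bouts$state[-nrow(bouts)] == from_state &
                 bouts$state[-1] == to_state)
  if (length(idx) == 0) {
    return(tibble(time = numeric(), from_state = character(),
                  to_state = character(), bout_duration_after = numeric(),
                  origin = character()))
  }
  out <- tibble(
    time = bouts$onset[idx + 1L],
    from_state = from_state, to_state = to_state,
    bout_duration_after = bouts$duration[idx + 1L]
  )
  out <- dplyr::filter(out, .data$bout_duration_after >= min_bout_after)
  out$origin <- "spontaneous"
  if (!is.null(stim_onsets) && nrow(out) > 0) {
    evoked <- vapply(out$time, function(t) {
      any(stim_onsets >= t - 35 & stim_onsets <= t)
    }, logical(1))
    out$origin[evoked] <- "evoked"
  }
  out
}

#' Detect intra-state EMG onsets (micro-awakenings, active-awake onsets)
#'
#' Within all seconds labelled `parent_state`, computes the per-second EMG
#' RMS and a threshold of `mean + k * SD` of that within-state metric
#' (`rule = "mean_plus_k_sd"`, the default reading of an EMG threshold of
#' the mean exceeding k times the SD; `rule = "k_sd"` uses `k * SD` alone).
#' Each run of supra-threshold parent-state seconds yields one onset at its
#' first second; runs closer than `refractory` seconds merge into one
#' onset. Onsets inside NREM are micro-awakenings, inside wake active-awake
#' onsets.
#'
#' @param emg Raw EMG vector.
#' @param rate EMG sampling rate (Hz).
#' @param seconds Tibble `time`, `state` at 1-s resolution.
#' @param parent_state `"nrem"` or `"wake"`.
#' @param k Threshold multiplier (default 10).
#' @param rule Threshold rule (see above).
#' @param refractory Minimum gap between distinct onsets in seconds.
#' @return Tibble `time`, `kind`, `parent_state`, `threshold`.
#' @export
detect_substate_onsets <- function(emg, rate, seconds, parent_state,
                                   k = 10, rule = c("mean_plus_k_sd", "k_sd"),
                                   refractory = 8) {
  rule <- match.arg(rule)
  metric <- emg_rms_per_second(emg, rate)
  n <- min(length(metric), nrow(seconds))
  in_state <- seconds$state[seq_len(n)] == parent_state
  if (sum(in_state) < 60) {
    abort(sprintf("need >= 60 s of %s for threshold estimation, have %d s",
                  parent_state, sum(in_state)))
  }
  m <- metric[seq_len(n)]
  mu <- mean(m[in_state]); s <- stats::sd(m[in_state])
  thr <- if (rule == "mean_plus_k_sd") mu + k * s else k * s
  above <- in_state & m > thr
  times <- seconds$time[seq_len(n)][above]
  kind <- if (parent_state == "nrem") "micro_awakening" else "active_awake_onset"
  if (length(times) == 0) {
    return(tibble(time = numeric(), kind = character(),
                  parent_state = character(), threshold = numeric()))
  }
  onsets <- times[c(TRUE, diff(times) >= refractory)]
  tibble(time = onsets, kind = kind, parent_state = parent_state,
         threshold = thr)
}

#' Score a recording end to end
#'
#' Convenience wrapper: [epoch_features()], [classify_epochs()] and the
#' per-second expansion in one call.
#'
#' @param rec An `fp_recording` with `eeg` and `emg` channels.
#' @param epoch_len Epoch length in seconds.
#' @param thresholds From [score_thresholds()].
#' @return An `fp_hypnogram`.
#' @export
score_sleep <- function(rec, epoch_len = 4, thresholds = score_thresholds()) {
  eeg <- rec$channels$eeg
  emg <- rec$channels$emg
  if (is.null(eeg) || is.null(emg)) abort("recording needs eeg and emg channels")
  if (eeg$rate != emg$rate) abort("eeg and emg must share one rate here")
  feats <- epoch_features(eeg$samples, emg$samples, eeg$rate, epoch_len)
  classify_epochs(feats, thresholds, epoch_len)
}

#' @export
print.fp_hypnogram <- function(x, ...) {
  cat(sprintf("<fp_hypnogram> %d epochs of %g s\n",
              nrow(x$epochs), x$epoch_len))
  print(dplyr::count(x$epochs, .data$state))
  invisible(x)
}

# ground-truth epoch labels: majority state per epoch (ties -> first second)
truth_epoch_labels <- function(seconds, epoch_len = 4) {
  n_ep <- floor(nrow(seconds) / epoch_len)
  vapply(seq_len(n_ep), function(i) {
    lab <- seconds$state[((i - 1) * epoch_len + 1):(i * epoch_len)]
    tab <- table(lab)
    if (max(tab) > epoch_len / 2) names(which.max(tab)) else lab[1]
  }, character(1))
}
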