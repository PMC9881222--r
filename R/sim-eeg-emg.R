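#' Simulate EEG and EMG channels from a hypnogram
#'
#' EEG is a sum of three band-limited Gaussian noise components — delta
#' (0.5-4 Hz), theta (6-9 Hz) and broadband — whose per-state weights come
#' from `config$band_powers`, so NREM is delta-dominated, REM
#' theta-dominated and wake intermediate with high muscle tone. EMG is
#' band-passed (10-100 Hz, capped below Nyquist) Gaussian noise whose
#' amplitude follows `config$emg_levels` (wake high, NREM low, REM atonia).
#' Optional EMG bursts (micro-awakenings in NREM, active-awake onsets in
#' wake) are placed at seeded positions well inside eligible bouts and
#' logged in the returned ground truth.
#'
#' @param hypnogram A [simulate_hypnogram()] result covering the requested
#'   duration.
#' @param config A [sim_config()].
#' @return List with `eeg`, `emg` (numeric vectors at `eeg_rate` /
#'   `emg_rate`), the rates, and `burst_onsets`, a tibble (`time`, `kind`,
#'   `parent_state`) of injected bursts.
#' @export
simulate_eeg_emg <- function(hypnogram, config) {
  stopifnot(inherits(hypnogram, "sim_hypnogram"))
  labs <- hypnogram$seconds$state
  if (!all(labs %in% STATES)) {
    abort(sprintf("unknown state label: %s",
                  paste(setdiff(unique(labs), STATES), collapse = ", ")))
  }
  dur <- length(labs)

  eeg <- with_stream(config$seed, "eeg", {
    make_eeg(labs, config$eeg_rate, config$band_powers)
  })

  bursts <- place_bursts(hypnogram, config)
  emg <- with_stream(config$seed, "emg", {
    make_emg(labs, config$emg_rate, config$emg_levels, bursts,
             config$emg_bursts)
  })

  list(eeg = eeg, emg = emg,
       eeg_rate = config$eeg_rate, emg_rate = config$emg_rate,
       burst_onsets = bursts)
}

# FFT band-limiting: numerically stable for narrow low bands at high rates
# (an IIR design at 0.5 Hz / 1 kHz puts poles too close to the unit circle)
band_noise <- function(n, rate, band) {
  hi <- min(band[2], 0.45 * rate)
  x <- rnorm(n)
  xf <- fft(x)
  f <- (seq_len(n) - 1L) / n * rate
  f <- pmin(f, rate - f) # two-sided spectrum folded to [0, rate/2]
  xf[f < band[1] | f > hi] <- 0 + 0i
  out <- Re(fft(xf, inverse = TRUE)) / n
  out / stats::sd(out)
}

make_eeg <- function(labs, rate, band_powers) {
  n <- length(labs) * rate
  delta <- band_noise(n, rate, c(0.5, 4))
  theta <- band_noise(n, rate, c(6, 9))
  broad <- rnorm(n)
  w <- vapply(STATES, function(s) band_powers[[s]], numeric(3))
  per_sec <- match(labs, STATES)
  wd <- rep(w["delta", per_sec], each = rate)
  wt <- rep(w["theta", per_sec], each = rate)
  wb <- rep(w["broad", per_sec], each = rate)
  wd * delta + wt * theta + wb * broad
}

make_emg <- function(labs, rate, emg_levels, bursts, burst_cfg) {
  n <- length(labs) * rate
  base <- band_noise(n, rate, c(10, 100))
  amp <- rep(emg_levels[labs], each = rate)
  if (nrow(bursts) > 0) {
    blen <- round(burst_cfg$duration * rate)
    for (i in seq_len(nrow(bursts))) {
      i0 <- round(bursts$time[i] * rate) + 1L
      idx <- i0:min(i0 + blen - 1L, n)
      amp[idx] <- amp[idx] * burst_cfg$gain
    }
  }
  base * amp
}

# seeded placement of EMG bursts: >=20 s into a bout, >=30 s spacing,
# bouts long enough to hold the burst plus margins
place_bursts <- function(hypnogram, config) {
  bc <- config$emg_bursts
  want <- list(nrem = bc$n_micro %||% 0, wake = bc$n_active %||% 0)
  rows <- list()
  with_stream(config$seed, "bursts", {
    for (ps in names(want)) {
      k <- want[[ps]]
      if (k <= 0) next
      cand <- dplyr::filter(hypnogram$bouts, .data$state == ps,
                            .data$duration >= 50)
      if (nrow(cand) == 0) {
        warn(sprintf("no %s bout long enough to host an EMG burst", ps))
        next
      }
      picks <- cand[sample.int(nrow(cand), min(k, nrow(cand))), ]
      if (nrow(picks) < k) {
        warn(sprintf("only %d of %d %s bursts placed", nrow(picks), k, ps))
      }
      rows[[ps]] <- tibble(
        time = floor(picks$onset + 20 +
                       runif(nrow(picks)) * (picks$duration - 40)),
        kind = if (ps == "nrem") "micro_awakening" else "active_awake_onset",
        parent_state = ps
      )
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(time = numeric(), kind = character(),
                  parent_state = character()))
  }
  arrange(out, .data$time)
}
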