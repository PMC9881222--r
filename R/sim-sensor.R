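#' Difference-of-exponentials response kernel
#'
#' `k(t) = A * (exp(-(t - latency)/decay_tau) - exp(-(t - latency)/rise_tau))`
#' for `t >= latency`, scaled so its maximum equals `A`. The analytic peak
#' sits at `latency + rise*decay/(decay - rise) * log(decay/rise)`.
#'
#' @param t Times in seconds (relative to the event onset).
#' @param amplitude Peak amplitude `A` (signed).
#' @param latency,rise_tau,decay_tau Kernel parameters in seconds
#'   (`decay_tau > rise_tau > 0`).
#' @return Numeric vector of kernel values (0 before `latency`).
#' @export
response_kernel <- function(t, amplitude, latency, rise_tau, decay_tau) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  tt <- t - latency
  out <- numeric(length(t))
  pos <- tt >= 0
  raw <- exp(-tt[pos] / decay_tau) - exp(-tt[pos] / rise_tau)
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  norm <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out[pos] <- amplitude * raw / norm
  out
}

#' Analytic peak time of the difference-of-exponentials kernel
#' @inheritParams response_kernel
#' @return Peak time in seconds after the event onset.
#' @export
kernel_peak_time <- function(latency, rise_tau, decay_tau) {
  latency + rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
}

# ratio-level response time course of one event for a given sensor kind
sensor_event_kernel <- function(t, kind, state, config) {
  if (kind == "lactate") {
    lk <- config$lactate_kernel
    return(
      response_kernel(t, lk$early_amp, lk$latency, lk$early_rise, lk$early_tau) +
        response_kernel(t, lk$late_amp, lk$latency + lk$late_delay,
                        lk$late_rise, lk$late_tau)
    )
  }
  p <- config$response_params[[kind]]
  if (is.null(p)) abort(sprintf("no response parameters for sensor kind `%s`", kind))
  amp <- unname(p$amplitude[state])
  k <- response_kernel(t, amp, p$latency, p$rise_tau, p$decay_tau)
  if (kind == "Laconic") {
    tp <- config$trough_params
    k <- k - response_kernel(t, tp$depth, tp$latency, tp$rise_tau, tp$trough_tau)
  }
  k
}

#' Simulate sensor channels with state-conditioned event responses
#'
#' Builds the fluorescence (or amperometric) channels of one recording. The
#' underlying ratio- (or percent-) level signal is a baseline with
#' photobleaching decay `exp(-t/bleach_tau)`, a slow additive drift, and
#' Gaussian noise; every opening stimulation adds a state-conditioned
#' difference-of-exponentials kernel (Laconic additionally carries an early
#' negative trough, lactate a bimodal early+late kernel). For FRET sensors
#' the ratio change `r(t)` is split anti-correlated across the channel pair:
#' the numerator channel is scaled by `1 + 0.6 r(t)` and the denominator by
#' `1 - 0.4 r(t)`, so the ratio carries `r(t)` to first order.
#'
#' @param hypnogram True hypnogram (states condition the amplitudes).
#' @param events Event tibble from [simulate_stim_protocol()]; responses are
#'   injected at `role == "opening"` events of kind `stim_blue` (control
#'   yellow-only events evoke nothing). If `config$respond_transitions` is
#'   `TRUE`, NREM-to-wake transitions of the true hypnogram also receive the
#'   `transition_response` kernel.
#' @param config A [sim_config()].
#' @param sensor_kind One of `"ATeam"`, `"Laconic"`, `"single"`,
#'   `"lactate"`.
#' @return List with `channels` (named list of numeric vectors), `rate`,
#'   `convention` (numerator/denominator channel names for FRET kinds), and
#'   `truth` (injected ratio-level signal and per-event parameters).
#' @export
simulate_sensor <- function(hypnogram, events, config, sensor_kind = "ATeam") {
  stopifnot(inherits(hypnogram, "sim_hypnogram"))
  if (!sensor_kind %in% c("ATeam", "Laconic", "single", "lactate")) {
    abort("sensor_kind must be ATeam, Laconic, single or lactate")
  }
  rate <- if (sensor_kind == "lactate") config$lactate_rate else config$photometry_rate
  dur <- nrow(hypnogram$seconds)
  n <- round(dur * rate)
  t <- (seq_len(n) - 1L) / rate
  if (nrow(events) > 0 && any(events$onset < 0 | events$onset >= dur)) {
    abort("event onsets must lie inside the recording")
  }

  # responding events: opening blue stimulations (+ optional transitions)
  resp <- dplyr::filter(events, .data$role == "opening",
                        .data$kind == "stim_blue")
  resp <- dplyr::select(resp, "onset", "state")
  resp$source <- rep("stim", nrow(resp))
  if (isTRUE(config$respond_transitions) && sensor_kind != "lactate") {
    tr <- transitions_from_bouts(hypnogram$bouts, "nrem", "wake")
    if (nrow(tr) > 0) {
      resp <- bind_rows(resp, tibble(onset = tr$time, state = "wake",
                                     source = "transition"))
    }
  }

  r <- numeric(n) # injected ratio-level signal
  horizon_s <- function(kind) {
    if (kind == "lactate") {
      lk <- config$lactate_kernel
      lk$latency + lk$late_delay + 8 * lk$late_tau
    } else {
      p <- config$response_params[[kind]]
      p$latency + 8 * p$decay_tau
    }
  }
  if (nrow(resp) > 0) {
    for (i in seq_len(nrow(resp))) {
      i0 <- round(resp$onset[i] * rate) + 1L
      i1 <- min(n, i0 + ceiling(horizon_s(sensor_kind) * rate))
      tt <- (seq(i0, i1) - i0) / rate
      kern <- if (resp$source[i] == "stim") {
        sensor_event_kernel(tt, sensor_kind, resp$state[i], config)
      } else {
        tp <- config$transition_response
        response_kernel(tt, tp$amplitude, tp$latency, tp$rise_tau, tp$decay_tau)
      }
      r[i0:i1] <- r[i0:i1] + kern
    }
  }

  bleach <- exp(-t / config$bleach_tau)
  drift <- with_stream(config$seed, "drift", slow_drift(n, config$drift_sd))

  channels <- with_stream(config$seed, "sensor", {
    if (sensor_kind %in% c("ATeam", "Laconic")) {
      sdc <- config$noise_sd[["photometry"]] / sqrt(2)
      num <- 2.0 * bleach * (1 + 0.6 * r) * (1 + drift) * (1 + rnorm(n, 0, sdc))
      den <- 1.0 * bleach * (1 - 0.4 * r) * (1 + drift) * (1 + rnorm(n, 0, sdc))
      if (sensor_kind == "ATeam") {
        list(mVenus = num, CFP = den)
      } else {
        list(CFP = num, mVenus = den) # Laconic ratio is CFP/mVenus
      }
    } else if (sensor_kind == "single") {
      sdc <- config$noise_sd[["photometry"]]
      list(F = 1.0 * bleach * (1 + r) * (1 + drift) * (1 + rnorm(n, 0, sdc)))
    } else {
      base <- 10 # nA
      sdc <- config$noise_sd[["lactate"]] / 100
      list(lactate = base * (1 + r / 100) * (1 + drift) *
             (1 + rnorm(n, 0, sdc)))
    }
  })

  convention <- switch(sensor_kind,
    ATeam = c(numerator = "mVenus", denominator = "CFP"),
    Laconic = c(numerator = "CFP", denominator = "mVenus"),
    NULL
  )
  list(channels = channels, rate = rate, convention = convention,
       truth = list(ratio_signal = r, events = resp,
                    params = if (sensor_kind == "lactate") {
                      config$lactate_kernel
                    } else {
                      config$response_params[[sensor_kind]]
                    }))
}

# slow additive drift: heavily smoothed random walk with relative SD sd_rel
slow_drift <- function(n, sd_rel) {
  if (sd_rel <= 0) return(numeric(n))
  k <- max(8L, min(n, 256L))
  coarse <- cumsum(rnorm(k))
  coarse <- coarse - mean(coarse)
  coarse <- coarse / max(stats::sd(coarse), .Machine$double.eps) * sd_rel
  approx(seq(0, 1, length.out = k), coarse, xout = seq(0, 1, length.out = n))$y
}

transitions_from_bouts <- function(bouts, from, to) {
  idx <- which(bouts$state[-nrow(bouts)] == from & bouts$state[-1] == to)
  tibble(time = bouts$onset[idx + 1L])
}
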