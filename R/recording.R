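#' Recording container for synchronized multichannel data
#'
#' Holds named channels (each a numeric sample vector with its own sampling
#' rate, units and kind), a sorted event log, and free-form metadata
#' (subject id, condition label such as "Pre"/"4-CIN"/"CNO"/"saline").
#' Times are seconds from recording start (0-based); an event occupies the
#' half-open interval `[onset, onset + duration)`.
#'
#' @param channels Named list; each element a list with `samples` (numeric),
#'   `rate` (Hz), `units`, and `kind` (one of `fluorescence`, `eeg`, `emg`,
#'   `amperometric`).
#' @param events Event tibble (columns `onset`, `duration`, `kind`, plus
#'   free attribute columns), sorted by onset.
#' @param start_time Start time in seconds (0 by default).
#' @param metadata Named list of free-form metadata.
#' @return An object of class `fp_recording`.
#' @export
fp_recording <- function(channels, events = empty_events(), start_time = 0,
                         metadata = list()) {
  rec <- structure(
    list(channels = channels, events = as_tibble(events),
         start_time = start_time, metadata = metadata),
    class = "fp_recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  ch <- rec$channels
  if (length(ch) == 0) abort("recording must contain at least one channel")
  if (is.null(names(ch)) || anyDuplicated(names(ch))) {
    abort("channel names must be present and unique")
  }
  for (nm in names(ch)) {
    c1 <- ch[[nm]]
    if (!is.numeric(c1$samples)) {
      abort(sprintf("channel `%s`: samples must be numeric", nm))
    }
    if (!is.numeric(c1$rate) || c1$rate <= 0) {
      abort(sprintf("channel `%s`: rate must be positive", nm))
    }
    if (!c1$kind %in% c("fluorescence", "eeg", "emg", "amperometric")) {
      abort(sprintf("channel `%s`: unknown kind `%s`", nm, c1$kind))
    }
  }
  ev <- rec$events
  if (nrow(ev) > 0) {
    if (is.unsorted(ev$onset)) abort("events: onsets must be sorted ascending")
    if (any(ev$duration < 0)) abort("events: durations must be >= 0")
    dur <- recording_duration(rec)
    if (any(ev$onset < 0) || any(ev$onset >= dur)) {
      abort("events: onsets must lie within the recording span")
    }
  }
  rec
}

#' Duration of a recording in seconds (longest channel)
#' @param rec An `fp_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  max(vapply(rec$channels,
             function(c1) length(c1$samples) / c1$rate, numeric(1)))
}

#' Extract one channel as a tidy trace
#'
#' @param rec An `fp_recording`.
#' @param name Channel name.
#' @return Tibble with columns `time` (s) and `value`.
#' @export
channel_trace <- function(rec, name) {
  c1 <- rec$channels[[name]]
  if (is.null(c1)) abort(sprintf("no channel named `%s`", name))
  tibble(time = rec$start_time + (seq_along(c1$samples) - 1) / c1$rate,
         value = c1$samples)
}

#' Ratiometric or single-channel sensor trace of a recording
#'
#' Builds the raw sensor time series the quantification pipeline starts
#' from: `mVenus/CFP` for the ATP sensor ATeam, `CFP/mVenus` for the
#' lactate sensor Laconic, the single fluorescence channel `F` for
#' intensity sensors, or the amperometric lactate channel.
#'
#' @param rec An `fp_recording` with `metadata$sensor` set (or pass
#'   `sensor`).
#' @param sensor Sensor kind override.
#' @return Tibble `time`, `value` at the sensor sampling rate.
#' @export
sensor_trace <- function(rec, sensor = NULL) {
  sensor <- sensor %||% rec$metadata$sensor
  if (is.null(sensor)) abort("sensor kind not given and absent from metadata")
  switch(sensor,
    ATeam = {
      num <- rec$channels$mVenus; den <- rec$channels$CFP
      tibble(time = (seq_along(num$samples) - 1) / num$rate,
             value = compute_ratio(num$samples, den$samples))
    },
    Laconic = {
      num <- rec$channels$CFP; den <- rec$channels$mVenus
      tibble(time = (seq_along(num$samples) - 1) / num$rate,
             value = compute_ratio(num$samples, den$samples))
    },
    single = channel_trace(rec, "F"),
    lactate = channel_trace(rec, "lactate"),
    abort(sprintf("unknown sensor kind `%s`", sensor))
  )
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %.1f s, %d channel(s), %d event(s)\n",
              recording_duration(x), length(x$channels), nrow(x$events)))
  for (nm in names(x$channels)) {
    c1 <- x$channels[[nm]]
    cat(sprintf("  %-8s %-12s %6g Hz  %d samples [%s]\n", nm, c1$kind,
                c1$rate, length(c1$samples), c1$units))
  }
  invisible(x)
}

#' Simulate a complete annotated recording
#'
#' End-to-end synthetic recording: hypnogram, stimulation protocol, EEG/EMG
#' and sensor channels, assembled into an [fp_recording()] whose ground
#' truth (true per-second labels, bouts, events, injected response
#' parameters, EMG burst onsets) is attached as attribute `ground_truth`.
#' When `config$stim$induce_awakening` is `TRUE`, each stimulation delivered
#' in NREM wakes the animal `wake_latency` s after the onset for roughly
#' `evoked_bout` s (an evoked awakening); EEG/EMG and the sensor follow the
#' modified hypnogram.
#'
#' @param config A [sim_config()].
#' @param sensor Sensor kind (`"ATeam"`, `"Laconic"`, `"single"`,
#'   `"lactate"`).
#' @param with_eeg Generate EEG/EMG channels (skip for speed when only the
#'   sensor is analyzed against ground-truth labels).
#' @return An `fp_recording` with attribute `ground_truth`.
#' @export
simulate_recording <- function(config, sensor = "ATeam", with_eeg = TRUE) {
  if (sensor == "lactate" && config$stim$min_interval < 420) {
    abort("lactate protocols require stim$min_interval >= 420 s")
  }
  hyp <- simulate_hypnogram(config)
  ev <- simulate_stim_protocol(hyp, config)
  if (isTRUE(config$stim$induce_awakening) && nrow(ev) > 0) {
    hyp <- insert_evoked_wake(hyp, ev, config)
  }
  sens <- simulate_sensor(hyp, ev, config, sensor)

  channels <- list()
  bursts <- tibble(time = numeric(), kind = character(),
                   parent_state = character())
  if (with_eeg) {
    ee <- simulate_eeg_emg(hyp, config)
    channels$eeg <- list(samples = ee$eeg, rate = ee$eeg_rate,
                         units = "uV", kind = "eeg")
    channels$emg <- list(samples = ee$emg, rate = ee$emg_rate,
                         units = "uV", kind = "emg")
    bursts <- ee$burst_onsets
  }
  for (nm in names(sens$channels)) {
    channels[[nm]] <- list(
      samples = sens$channels[[nm]], rate = sens$rate,
      units = if (sensor == "lactate") "nA" else "a.u.",
      kind = if (sensor == "lactate") "amperometric" else "fluorescence"
    )
  }

  rec <- fp_recording(channels, events = ev,
                      metadata = list(sensor = sensor,
                                      seed = config$seed,
                                      control = isTRUE(config$stim$control)))
  attr(rec, "ground_truth") <- list(
    hypnogram = hyp,
    events = ev,
    response_params = sens$truth$params,
    ratio_signal = sens$truth$ratio_signal,
    burst_onsets = bursts,
    config = config
  )
  rec
}

# overwrite hypnogram seconds with evoked wake bouts after NREM stimulations
insert_evoked_wake <- function(hyp, ev, config) {
  st <- config$stim
  labs <- hyp$seconds$state
  opening <- dplyr::filter(ev, .data$role == "opening", .data$state == "nrem")
  if (nrow(opening) == 0) return(hyp)
  lens <- with_stream(config$seed, "misc", {
    pmax(35, round(rexp(nrow(opening), 1 / st$evoked_bout)))
  })
  for (i in seq_len(nrow(opening))) {
    i0 <- floor(opening$onset[i]) + 1L + st$wake_latency
    i1 <- min(length(labs), i0 + lens[i] - 1L)
    if (i0 <= length(labs)) labs[i0:i1] <- "wake"
  }
  hyp$seconds$state <- labs
  hyp$bouts <- labels_to_bouts(labs)
  hyp
}
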