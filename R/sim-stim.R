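#' Simulate the optogenetic stimulation protocol
#'
#' Places stimulation pairs inside bouts of the target vigilance state: each
#' stimulation is a 1-s blue-light event (channel opening) followed by a 1-s
#' yellow-light event (closing) 30 s later. Gating uses the true hypnogram
#' (the experimental analogue is online visual judgment of EEG/EMG): an
#' onset requires the animal to have been in the target state for at least
#' `stim$settle` seconds, successive onsets are at least `stim$min_interval`
#' seconds apart, and the full blue+yellow pair must fit in the recording.
#' In the control condition yellow light is used in place of blue, so both
#' events of a pair are yellow.
#'
#' @param hypnogram A [simulate_hypnogram()] result.
#' @param config A [sim_config()]; `config$stim` holds the protocol.
#' @return An event tibble with columns `onset`, `duration`, `kind`
#'   (`stim_blue`/`stim_yellow`), `stim_id`, `role` (`opening`/`closing`)
#'   and `state` (true state at onset). Empty (with a warning) when no
#'   eligible bout exists; a warning is also raised when fewer than the
#'   requested number of stimulations fit.
#' @export
simulate_stim_protocol <- function(hypnogram, config) {
  stopifnot(inherits(hypnogram, "sim_hypnogram"))
  st <- config$stim
  labs <- hypnogram$seconds$state
  dur <- length(labs)
  target <- st$target_state
  if (st$n_per_session < 1) return(empty_events())

  # seconds at which the animal has been in the target state >= settle s
  in_target <- labs == target
  run <- integer(dur)
  cnt <- 0L
  for (i in seq_len(dur)) {
    cnt <- if (in_target[i]) cnt + 1L else 0L
    run[i] <- cnt
  }
  tail_needed <- st$yellow_offset + st$yellow_dur
  eligible <- which(run > st$settle & seq_len(dur) - 1L + tail_needed < dur) - 1L

  if (length(eligible) == 0) {
    warn(sprintf("no eligible %s bout for stimulation; empty event set", target))
    return(empty_events())
  }

  onsets <- numeric(0)
  t_next <- -Inf
  for (t in eligible) {
    if (t >= t_next) {
      onsets <- c(onsets, t)
      t_next <- t + st$min_interval
      if (length(onsets) >= st$n_per_session) break
    }
  }
  if (length(onsets) < st$n_per_session) {
    warn(sprintf("placed %d of %d requested stimulations in %s bouts",
                 length(onsets), st$n_per_session, target))
  }

  first_kind <- if (isTRUE(st$control)) "stim_yellow" else "stim_blue"
  ev <- bind_rows(
    tibble(onset = onsets, duration = st$blue_dur, kind = first_kind,
           stim_id = seq_along(onsets), role = "opening",
           state = labs[onsets + 1L]),
    tibble(onset = onsets + st$yellow_offset, duration = st$yellow_dur,
           kind = "stim_yellow", stim_id = seq_along(onsets),
           role = "closing", state = labs[pmin(onsets + st$yellow_offset, dur - 1) + 1L])
  )
  arrange(ev, .data$onset)
}

empty_events <- function() {
  tibble(onset = numeric(), duration = numeric(), kind = character(),
         stim_id = integer(), role = character(), state = character())
}
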