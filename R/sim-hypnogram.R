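#' Simulate a per-second hypnogram
#'
#' Draws an alternating sequence of vigilance-state bouts from a semi-Markov
#' surrogate of mouse sleep architecture: bout lengths are exponential with
#' the configured state means (rounded to whole seconds, floored at
#' `min_bout`), wake is followed by NREM, NREM by REM with probability
#' `rem_entry_prob` (else wake), and REM always returns to wake. States with
#' a zero dwell mean are never entered, so REM is only reachable from NREM.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_hypnogram` with elements `seconds` (tibble
#'   `time`, `state`; one row per second of `[0, duration)`), `bouts`
#'   (tibble `state`, `onset`, `duration` — the ground-truth dwell record)
#'   and `epoch_len = 1`.
#' @export
simulate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dur <- as.integer(ceiling(config$duration))
  if (dur <= 0) abort("duration must be positive")
  dm <- config$state_dwell_means[STATES]
  dm[is.na(dm)] <- 0
  names(dm) <- STATES
  avail <- names(dm)[dm > 0]

  labels <- with_stream(config$seed, "hypnogram", {
    out <- character(0)
    # start in the longest-dwelling available state (wake if present)
    state <- if ("wake" %in% avail) "wake" else avail[[1L]]
    while (length(out) < dur) {
      len <- max(config$min_bout, round(rexp(1L, rate = 1 / dm[[state]])))
      out <- c(out, rep(state, len))
      state <- next_state(state, avail, config$rem_entry_prob)
    }
    out[seq_len(dur)]
  })

  structure(
    list(
      seconds = tibble(time = seq_len(dur) - 1L, state = labels),
      bouts = labels_to_bouts(labels),
      epoch_len = 1L
    ),
    class = "sim_hypnogram"
  )
}

next_state <- function(state, avail, rem_entry_prob) {
  if (length(avail) == 1L) return(avail)
  if (state == "wake") {
    if ("nrem" %in% avail) "nrem" else "wake"
  } else if (state == "nrem") {
    if ("rem" %in% avail && runif(1L) < rem_entry_prob) {
      "rem"
    } else if ("wake" %in% avail) "wake" else "nrem"
  } else { # rem
    if ("wake" %in% avail) "wake" else "nrem"
  }
}

# state label at integer second floor(t); times beyond the end clamp to last
state_at <- function(hypnogram, t) {
  labs <- hypnogram$seconds$state
  idx <- pmin(pmax(floor(t) + 1L, 1L), length(labs))
  labs[idx]
}

#' @export
print.sim_hypnogram <- function(x, ...) {
  cat(sprintf("<sim_hypnogram> %d s, %d bouts\n",
              nrow(x$seconds), nrow(x$bouts)))
  print(dplyr::count(x$seconds, .data$state))
  invisible(x)
}
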