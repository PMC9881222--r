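#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of first last lag lead
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rnorm rexp runif sd median approx fft integrate pchisq
#'   pnorm ptukey qnorm quantile setNames
NULL

STATES <- c("wake", "nrem", "rem")

# deterministic per-stream seed derivation: one user seed fans out into
# independent sub-streams so each generator op is reproducible on its own
sim_stream_seed <- function(seed, stream) {
  offs <- c(
    hypnogram = 11L, eeg = 23L, emg = 37L, stim = 53L, sensor = 71L,
    drift = 89L, bursts = 101L, misc = 113L
  )
  off <- offs[[stream]]
  (as.integer(seed) %% 21474836L) * 97L + off
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(sim_stream_seed(seed, stream), code)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

is_trace_frame <- function(x) {
  is.data.frame(x) && all(c("time", "value") %in% names(x))
}

assert_trace <- function(x, name = "trace") {
  if (!is_trace_frame(x)) {
    abort(sprintf("`%s` must be a data frame with columns `time` and `value`", name))
  }
  invisible(x)
}

# run-length bouts from a per-second label vector (time starts at t0)
labels_to_bouts <- function(labels, t0 = 0) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(
    state = r$values,
    onset = t0 + starts,
    duration = r$lengths
  )
}
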