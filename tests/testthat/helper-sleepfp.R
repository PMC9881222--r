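# shared fixtures: test-suite configs run EEG/EMG at 200 Hz and photometry
# at 100 Hz (full-fidelity 1 kHz stays the package default); smoothing
# windows scale with rate, so the 0.1-s/0.5-s filters are 10/50 points here
test_config <- function(seed = 1, duration = 1800, ...) {
  sim_config(seed = seed, duration = duration,
             eeg_rate = 200, emg_rate = 200, photometry_rate = 100, ...)
}

TEST_PHOT_RATE <- 100
SMOOTH_PTS <- 50L   # 0.5 s at 100 Hz
FILTER_PTS <- 10L   # 0.1 s at 100 Hz

stim_metric_spec <- function(mode = "peak") {
  list(smooth_points = SMOOTH_PTS, auc_window = c(0, 30),
       auc_exclusions = list(c(0, 1), c(30, 31)),
       peak_window = c(1, 120), mode = mode)
}

# quantify one simulated stimulation recording into an fp_session
quantify_test_session <- function(rec, mode = "peak", session_id = NA,
                                  condition = NA) {
  tr <- sensor_trace(rec)
  tr$value <- moving_average(tr$value, FILTER_PTS)
  opening <- dplyr::filter(rec$events, role == "opening")
  ens <- extract_snippets(tr, opening, pre = 10, post = 120,
                          baseline_dur = 5, mode = "delta")
  session_average(ens, design = "stim", metric_spec = stim_metric_spec(mode),
                  session_id = session_id, condition = condition)
}

# independent oracle: trapezoid on a 10x-oversampled linear interpolation of
# the trace, over the window minus exclusion intervals
riemann_auc_oracle <- function(trace, window, exclusions) {
  fine_segment <- function(a, b) {
    if (b <= a) return(0)
    xs <- sort(unique(c(seq(a, b, length.out = 10 * 29 + 1),
                        trace$time[trace$time >= a & trace$time <= b])))
    ys <- approx(trace$time, trace$value, xout = xs)$y
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  }
  total <- fine_segment(window[1], window[2])
  for (e in exclusions %||% list()) {
    total <- total - fine_segment(max(e[1], window[1]), min(e[2], window[2]))
  }
  total
}

# independent enumeration oracle for the signed-rank exact p
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  mu <- sum(r) / 2
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# independent permutation oracle for the Mann-Whitney exact p
mann_whitney_perm_oracle <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

`%||%` <- rlang::`%||%`
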