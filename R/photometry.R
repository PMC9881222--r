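#' Centered moving average with truncated edges
#'
#' The smoothing applied to raw sensor signals before display and
#' quantification: a 100-point window for trace construction and a 500-point
#' window before peak/trough/AUC extraction (both at 1 kHz; pass the
#' equivalent point count at other rates). The window is centered on each
#' sample; near the edges the window truncates to the available samples, so
#' the output length equals the input length and constants are left
#' unchanged.
#'
#' @param x Numeric vector.
#' @param window_points Window width in samples (>= 1). Even widths place
#'   the extra sample after the center.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window_points) {
  if (length(x) == 0) abort("empty input")
  w <- as.integer(window_points)
  if (w < 1 || w > length(x)) abort("window_points must be in [1, length(x)]")
  if (w == 1) return(as.numeric(x))
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' FRET ratio from a channel pair
#'
#' Elementwise ratio of two equally sampled fluorescence channels
#' (`mVenus/CFP` for ATeam, `CFP/mVenus` for Laconic). The denominator must
#' stay above `eps` (default `1e-6` times its median) everywhere.
#'
#' @param numerator,denominator Equal-length numeric channels.
#' @param eps Smallest admissible denominator value.
#' @return Numeric ratio vector.
#' @export
compute_ratio <- function(numerator, denominator,
                          eps = 1e-6 * stats::median(denominator)) {
  if (length(numerator) != length(denominator)) {
    abort("numerator and denominator must have equal length")
  }
  bad <- which(denominator <= eps)
  if (length(bad) > 0) {
    abort(sprintf("denominator <= eps at index %d", bad[1]))
  }
  numerator / denominator
}

#' Baseline-normalize a trace around an anchor
#'
#' Computes the pre-event baseline `X0` as the mean of the trace over
#' `[anchor_time - baseline_dur, anchor_time)` — 5 s before light
#' illumination or a state transition, 4 s (one epoch) before sub-state
#' onsets — and returns `(X - X0)/X0` (`mode = "delta"`, i.e. dR/R or
#' dF/F), `100 * X / X0` (`mode = "percent"`, used for extracellular
#' lactate), or `X - X0` (`mode = "shift"`, zero-point adjustment without
#' division).
#'
#' @param trace Tibble with `time`, `value`.
#' @param anchor_time Anchor (event onset / transition time) in seconds.
#' @param baseline_dur Baseline window length in seconds (default 5).
#' @param mode `"delta"`, `"percent"` or `"shift"`.
#' @return Tibble `time`, `value` with `time` re-expressed relative to the
#'   anchor.
#' @export
normalize_trace <- function(trace, anchor_time, baseline_dur = 5,
                            mode = c("delta", "percent", "shift")) {
  assert_trace(trace)
  mode <- match.arg(mode)
  t <- trace$time
  in_base <- t >= (anchor_time - baseline_dur) & t < anchor_time
  if (!any(in_base)) abort("baseline window lies outside the trace")
  if (min(t) > anchor_time - baseline_dur) {
    abort("baseline window extends before the start of the trace")
  }
  x0 <- mean(trace$value[in_base])
  if (mode != "shift" && x0 == 0) abort("baseline mean is zero")
  value <- switch(mode,
    delta = (trace$value - x0) / x0,
    percent = 100 * trace$value / x0,
    shift = trace$value - x0
  )
  tibble(time = t - anchor_time, value = value)
}

# trapezoidal integral of the piecewise-linear trace over [a, b], with
# linear interpolation at the interval ends
trapz_interval <- function(time, value, a, b) {
  if (b <= a) return(0)
  a <- max(a, min(time)); b <- min(b, max(time))
  if (b <= a) return(0)
  inside <- which(time > a & time < b)
  ts <- c(a, time[inside], b)
  vs <- c(approx(time, value, xout = a)$y, value[inside],
          approx(time, value, xout = b)$y)
  sum(diff(ts) * (utils::head(vs, -1) + utils::tail(vs, -1)) / 2)
}

#' Signed area under the curve over a window, minus exclusions
#'
#' Trapezoidal integral of a normalized trace over `window`, subtracting the
#' integral over each exclusion interval (clipped to the window). The
#' default stimulation analysis integrates the 30-s illumination period
#' excluding 1 s at each light exposure: window `[0, 30]` with exclusions
#' `[0, 1]` and `[30, 31]`, i.e. an effective `[1, 30)` of width 29 s.
#' Lactate phases use windows `[0, 30]` (early) and `[30, 400]` (late)
#' without exclusions.
#'
#' @param trace Tibble `time`, `value` with time relative to the anchor.
#' @param window Length-2 numeric, integration window in seconds.
#' @param exclusions List of length-2 intervals to exclude (or `NULL`).
#' @param ref Reference level subtracted before integration (0 for dR/R,
#'   100 for percent-normalized lactate).
#' @return Signed AUC in value-units times seconds.
#' @export
windowed_auc <- function(trace, window = c(0, 30),
                         exclusions = list(c(0, 1), c(30, 31)), ref = 0) {
  assert_trace(trace)
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be an increasing length-2 numeric")
  }
  t <- trace$time
  v <- trace$value - ref
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9) {
    abort("window extends beyond the trace")
  }
  total <- trapz_interval(t, v, window[1], window[2])
  excl <- 0
  width_excluded <- 0
  for (e in exclusions %||% list()) {
    a <- max(e[1], window[1]); b <- min(e[2], window[2])
    if (b > a) {
      excl <- excl + trapz_interval(t, v, a, b)
      width_excluded <- width_excluded + (b - a)
    }
  }
  if (width_excluded >= diff(window)) abort("exclusions cover the whole window")
  total - excl
}

#' Positive and negative AUC components
#'
#' Splits the windowed integral into the areas of the positive and negative
#' parts of the trace (relative to `ref`), as used when a response carries a
#' transient dip: the two parts always sum to the plain [windowed_auc()]
#' over the same window without exclusions.
#'
#' @inheritParams windowed_auc
#' @return Tibble with `auc_positive`, `auc_negative` (negative number) and
#'   `auc_total`.
#' @export
split_signed_auc <- function(trace, window, ref = 0) {
  assert_trace(trace)
  v <- trace$value - ref
  pos <- tibble(time = trace$time, value = pmax(v, 0))
  neg <- tibble(time = trace$time, value = pmin(v, 0))
  tibble(
    auc_positive = windowed_auc(pos, window, exclusions = NULL),
    auc_negative = windowed_auc(neg, window, exclusions = NULL),
    auc_total = windowed_auc(tibble(time = trace$time, value = v),
                             window, exclusions = NULL)
  )
}

#' Peak / trough extraction
#'
#' Locates extrema of a (500-point-smoothed) normalized trace inside a
#' search window. `mode = "peak"` returns the maximum, `"trough"` the
#' minimum. `mode = "biphasic"` handles trough-then-peak responses (initial
#' trough followed by an increase): the global maximum time `t_p` is found
#' first, the trough is the minimum over `[window start, t_p]`, and the peak
#' is then re-searched over `[trough time, window end]`, which guarantees
#' `trough_time < peak_time`. Ties break toward the earliest time; an
#' all-constant trace is reported with a flatness warning.
#'
#' @param trace Tibble `time`, `value` (time relative to anchor).
#' @param window Length-2 search window in seconds.
#' @param mode `"peak"`, `"trough"` or `"biphasic"`.
#' @return One-row tibble with `peak_value`, `peak_time`, `trough_value`,
#'   `trough_time` (unused fields `NA`).
#' @export
find_extrema <- function(trace, window = c(1, 120),
                         mode = c("peak", "trough", "biphasic")) {
  assert_trace(trace)
  mode <- match.arg(mode)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) abort("search window contains no samples")
  t <- trace$time[sel]
  v <- trace$value[sel]
  if (diff(range(v)) == 0) warn("trace is flat over the search window")
  res <- tibble(peak_value = NA_real_, peak_time = NA_real_,
                trough_value = NA_real_, trough_time = NA_real_)
  if (mode == "peak") {
    i <- which.max(v)
    res$peak_value <- v[i]; res$peak_time <- t[i]
  } else if (mode == "trough") {
    i <- which.min(v)
    res$trough_value <- v[i]; res$trough_time <- t[i]
  } else {
    ip <- which.max(v)
    pre <- seq_len(ip)
    it <- pre[which.min(v[pre])]
    post <- it:length(v)
    ip2 <- post[which.max(v[post])]
    res$trough_value <- v[it]; res$trough_time <- t[it]
    res$peak_value <- v[ip2]; res$peak_time <- t[ip2]
  }
  res
}

#' Response metric bundle for one trace
#'
#' Convenience wrapper computing the standard metric set on an
#' already-normalized, already-smoothed trace: the stimulation AUC
#' (30-s window minus the two 1-s illumination exclusions), extrema in the
#' configured search window, and optional phase AUCs (e.g. the early
#' 0-30 s / late 30-400 s lactate phases).
#'
#' @param trace Normalized, smoothed tibble `time`, `value`.
#' @param auc_window,auc_exclusions Passed to [windowed_auc()].
#' @param peak_window,mode Passed to [find_extrema()].
#' @param phases Named list of phase windows for per-phase AUCs (or `NULL`).
#' @param ref Reference level (see [windowed_auc()]).
#' @return One-row tibble of metrics (`auc`, extrema, one `auc_<phase>`
#'   column per phase).
#' @export
response_metrics <- function(trace, auc_window = c(0, 30),
                             auc_exclusions = list(c(0, 1), c(30, 31)),
                             peak_window = c(1, 120), mode = "peak",
                             phases = NULL, ref = 0) {
  out <- dplyr::bind_cols(
    tibble(auc = windowed_auc(trace, auc_window, auc_exclusions, ref = ref)),
    find_extrema(trace, peak_window, mode)
  )
  for (ph in names(phases %||% list())) {
    out[[paste0("auc_", ph)]] <-
      windowed_auc(trace, phases[[ph]], exclusions = NULL, ref = ref)
  }
  out
}
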