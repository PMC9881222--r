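#' Extract event-aligned, baseline-normalized snippets
#'
#' Cuts one snippet per event from a uniformly sampled trace, covering
#' `[-pre, +post]` seconds around each onset, and normalizes each snippet to
#' its own pre-event baseline (the mean over `[onset - baseline_dur,
#' onset)`; see [normalize_trace()] for the modes). Events whose snippet or
#' baseline window does not fit inside the trace are skipped with a
#' message. The input trace should already carry the display filter
#' (100-point moving average at 1 kHz) when FRET/intensity signals are
#' analyzed.
#'
#' @param trace Tibble `time`, `value`, uniformly sampled.
#' @param events Event tibble (uses `onset`; other columns are kept in the
#'   ensemble's event table), or a numeric vector of onsets.
#' @param pre,post Snippet extent in seconds around the anchor.
#' @param baseline_dur Baseline window length (s) before the anchor.
#' @param mode Normalization mode: `"delta"` ((X - X0)/X0), `"percent"`
#'   (100 X / X0), `"shift"` (X - X0) or `"none"`.
#' @return An object of class `fp_ensemble`: list with `snippets` (matrix,
#'   events x samples), `time` (relative time axis, 0 = anchor), `events`
#'   (kept event rows), `n_events`, plus the window/normalization
#'   parameters. Use [as_tibble()] for the long view.
#' @export
extract_snippets <- function(trace, events, pre = 10, post = 120,
                             baseline_dur = 5,
                             mode = c("delta", "percent", "shift", "none")) {
  assert_trace(trace)
  mode <- match.arg(mode)
  if (is.numeric(events)) events <- tibble(onset = events)
  events <- arrange(as_tibble(events), .data$onset)
  if (nrow(events) == 0) abort("no events to align to")
  dts <- diff(trace$time)
  if (length(dts) < 1 || diff(range(dts)) > 1e-6 * dts[1]) {
    abort("trace must be uniformly sampled")
  }
  rate <- 1 / dts[1]
  t0 <- trace$time[1]
  v <- trace$value
  n <- length(v)
  pre_n <- round(pre * rate)
  post_n <- round(post * rate)
  base_n <- max(1L, round(baseline_dur * rate))
  rel <- seq.int(-pre_n, post_n)

  keep <- logical(nrow(events))
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    i_on <- round((on - t0) * rate) + 1L
    if (i_on - max(pre_n, base_n) < 1L || i_on + post_n > n) {
      inform(sprintf("event at t=%g s skipped: window out of bounds", on))
      next
    }
    snip <- v[i_on + rel]
    if (mode != "none") {
      x0 <- mean(v[(i_on - base_n):(i_on - 1L)])
      if (mode != "shift" && x0 == 0) abort("baseline mean is zero")
      snip <- switch(mode,
        delta = (snip - x0) / x0,
        percent = 100 * snip / x0,
        shift = snip - x0
      )
    }
    keep[i] <- TRUE
    rows[[i]] <- snip
  }
  if (!any(keep)) abort("zero usable events after bounds filtering")
  structure(
    list(snippets = do.call(rbind, rows[keep]),
         time = rel / rate,
         events = events[keep, , drop = FALSE],
         n_events = sum(keep),
         pre = pre, post = post, baseline_dur = baseline_dur, mode = mode),
    class = "fp_ensemble"
  )
}

#' @export
print.fp_ensemble <- function(x, ...) {
  cat(sprintf("<fp_ensemble> %d event(s), window [-%g, +%g] s, mode %s\n",
              x$n_events, x$pre, x$post, x$mode))
  invisible(x)
}

ensemble_long <- function(x) {
  ne <- x$n_events
  nt <- length(x$time)
  dplyr::bind_cols(
    x$events[rep(seq_len(ne), each = nt), , drop = FALSE],
    tibble(event_id = rep(seq_len(ne), each = nt),
           time = rep(x$time, times = ne),
           value = as.vector(t(x$snippets)))
  )
}

#' Session average of an event-aligned ensemble
#'
#' Pointwise mean across events, with the study's session validity rules:
#' a stimulation session needs at least `min_events` (default 3)
#' stimulations; a transition session is the 30-minute measurement with at
#' least one event. Invalid sessions are returned flagged, never silently
#' dropped. When a `metric_spec` is given, the session metrics are computed
#' on the smoothed session-mean trace.
#'
#' @param ensemble An `fp_ensemble`.
#' @param design `"stim"` or `"transition"`.
#' @param min_events Override the design's validity threshold (`>= 3` for
#'   stimulation sessions by default; set 4 for a strict more-than-3
#'   reading).
#' @param metric_spec Optional list of arguments for [response_metrics()]
#'   plus `smooth_points` (the 500-point-equivalent smoothing window).
#' @param session_id,condition Labels carried into the summary.
#' @return An object of class `fp_session`: list with `trace` (tibble
#'   `time`, `mean`), `n_events`, `valid`, `reason`, `metrics` (or `NULL`),
#'   `session_id`, `condition`.
#' @export
session_average <- function(ensemble, design = c("stim", "transition"),
                            min_events = NULL, metric_spec = NULL,
                            session_id = NA_character_,
                            condition = NA_character_) {
  stopifnot(inherits(ensemble, "fp_ensemble"))
  design <- match.arg(design)
  min_events <- min_events %||% if (design == "stim") 3L else 1L
  tr <- tibble(time = ensemble$time, mean = colMeans(ensemble$snippets))
  valid <- ensemble$n_events >= min_events
  reason <- if (valid) NA_character_ else sprintf("n_events<%d", min_events)
  metrics <- NULL
  if (!is.null(metric_spec)) {
    sp <- metric_spec$smooth_points %||% 1L
    sm <- moving_average(tr$mean, min(sp, nrow(tr)))
    args <- metric_spec[setdiff(names(metric_spec), "smooth_points")]
    metrics <- do.call(response_metrics,
                       c(list(trace = tibble(time = tr$time, value = sm)),
                         args))
  }
  structure(
    list(trace = tr, n_events = ensemble$n_events, valid = valid,
         reason = reason, metrics = metrics,
         session_id = session_id, condition = condition),
    class = "fp_session"
  )
}

#' @export
print.fp_session <- function(x, ...) {
  cat(sprintf("<fp_session> %s | %d event(s) | %s\n",
              x$session_id, x$n_events,
              if (x$valid) "valid" else paste("invalid:", x$reason)))
  invisible(x)
}

#' Group average across sessions
#'
#' Pointwise mean and SEM across the mean traces of the valid sessions (the
#' session is the unit of statistical analysis), plus a per-session metric
#' table for the downstream tests. At least two valid sessions are
#' required; `n` reports valid sessions only.
#'
#' @param sessions List of `fp_session` objects sharing one time axis.
#' @return List of class `fp_group`: `trace` (tibble `time`, `mean`, `sem`,
#'   `n`), `metrics` (one row per valid session), `n_sessions`,
#'   `n_excluded`.
#' @export
group_average <- function(sessions) {
  valid <- purrr::keep(sessions, ~ isTRUE(.x$valid))
  if (length(valid) < 2) abort("need at least 2 valid sessions")
  lens <- vapply(valid, function(s) nrow(s$trace), integer(1))
  if (length(unique(lens)) != 1L) {
    abort("sessions must share one snippet time axis")
  }
  m <- vapply(valid, function(s) s$trace$mean, numeric(lens[1]))
  k <- ncol(m)
  mu <- rowMeans(m)
  sdv <- sqrt(pmax(0, (rowSums(m^2) - k * mu^2) / (k - 1)))
  tr <- tibble(time = valid[[1]]$trace$time, mean = mu,
               sem = sdv / sqrt(k), n = k)
  metrics <- purrr::map_dfr(valid, function(s) {
    dplyr::bind_cols(
      tibble(session_id = s$session_id, condition = s$condition,
             n_events = s$n_events),
      s$metrics %||% tibble(.rows = 1)
    )
  })
  structure(
    list(trace = tr, metrics = metrics, n_sessions = length(valid),
         n_excluded = length(sessions) - length(valid)),
    class = "fp_group"
  )
}

#' Pair per-session metrics across two conditions
#'
#' Aligns one metric across two conditions by a pairing key (mouse or
#' session id) for paired tests; keys present in only one condition are
#' dropped with a warning naming them.
#'
#' @param metric_table Tibble with at least the pairing key, a `condition`
#'   column and the metric column.
#' @param condition_a,condition_b Condition labels (a is the reference,
#'   e.g. "Pre").
#' @param pairing_key Column name used to pair rows.
#' @param metric Metric column name.
#' @return List with numeric vectors `a`, `b` (key-aligned), `keys`, and
#'   `unpaired`.
#' @export
pair_conditions <- function(metric_table, condition_a, condition_b,
                            pairing_key = "session_id", metric = "auc") {
  tab <- as_tibble(metric_table)
  need <- c(pairing_key, "condition", metric)
  if (!all(need %in% names(tab))) {
    abort(sprintf("metric table must contain columns: %s",
                  paste(need, collapse = ", ")))
  }
  a_tab <- dplyr::filter(tab, .data$condition == condition_a)
  b_tab <- dplyr::filter(tab, .data$condition == condition_b)
  keys <- sort(intersect(a_tab[[pairing_key]], b_tab[[pairing_key]]))
  unpaired <- sort(setdiff(union(a_tab[[pairing_key]], b_tab[[pairing_key]]),
                           keys))
  if (length(keys) == 0) abort("zero complete pairs across the two conditions")
  if (length(unpaired) > 0) {
    warn(sprintf("unpaired keys dropped: %s", paste(unpaired, collapse = ", ")))
  }
  a <- a_tab[[metric]][match(keys, a_tab[[pairing_key]])]
  b <- b_tab[[metric]][match(keys, b_tab[[pairing_key]])]
  list(a = a, b = b, keys = keys, unpaired = unpaired)
}
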