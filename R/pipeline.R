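#' Analysis plan for an end-to-end run
#'
#' Describes one figure-style comparison on synthetic data: which design,
#' which sensor, how many sessions, and the effect parameters of the
#' non-reference condition.
#'
#' Designs:
#' * `stim_vs_control` — per session one stimulation recording and one
#'   control recording (yellow light in place of blue, which evokes no
#'   response); paired Wilcoxon on the session AUC.
#' * `pre_vs_drug` — per session a "Pre" and a "Drug" recording whose
#'   stimulation-locked amplitude is scaled by `effect_scale`; paired
#'   Wilcoxon on the AUC.
#' * `state_comparison` — per session one recording per target state (wake,
#'   NREM, REM; the REM recording is longer because REM bouts are scarce);
#'   Friedman across states plus Steel-Dwass all-pairs on the session-mean
#'   peak.
#' * `evoked_vs_spontaneous` — one long recording per session with
#'   stimulation-induced awakenings and transition-locked responses;
#'   NREM-to-wake transitions are split into evoked (stimulation within
#'   35 s) and spontaneous (wake lasting >= 30 s), and their session-mean
#'   peaks compared by paired Wilcoxon.
#' * `transition_saline_vs_cno` — per session a saline and a CNO 30-min
#'   recording without photostimulation; the transition-locked response
#'   amplitude is scaled by `effect_scale` under CNO; paired Wilcoxon on
#'   the transition peak.
#'
#' @param design One of the designs above.
#' @param sensor Sensor kind (see [simulate_sensor()]).
#' @param n_sessions Sessions (= mice) per condition.
#' @param duration Recording duration (s) per condition recording.
#' @param rem_duration Duration of REM-targeted recordings
#'   (`state_comparison` only).
#' @param effect_scale Amplitude scale of the non-reference condition.
#' @param n_stim Stimulations requested per session.
#' @param photometry_rate Sensor sampling rate for the simulated sessions.
#' @param eeg_rate EEG/EMG sampling rate for simulated sessions (used when
#'   `scored = TRUE`).
#' @param scored Use the EEG/EMG scorer for state labels (full stack);
#'   otherwise the generator's ground-truth labels are used and EEG/EMG
#'   synthesis is skipped.
#' @param metric Metric column the test runs on (`"auc"`, `"peak_value"`,
#'   ...).
#' @return A list of class `fp_plan`.
#' @export
analysis_plan <- function(design = c("stim_vs_control", "pre_vs_drug",
                                     "state_comparison",
                                     "evoked_vs_spontaneous",
                                     "transition_saline_vs_cno"),
                          sensor = "ATeam", n_sessions = 5,
                          duration = 1800, rem_duration = 5400,
                          effect_scale = 0.3, n_stim = 3,
                          photometry_rate = 1000, eeg_rate = 1000,
                          scored = FALSE, metric = NULL) {
  design <- match.arg(design)
  metric <- metric %||%
    if (design %in% c("state_comparison", "evoked_vs_spontaneous",
                      "transition_saline_vs_cno")) "peak_value" else "auc"
  structure(
    list(design = design, sensor = sensor, n_sessions = n_sessions,
         duration = duration, rem_duration = rem_duration,
         effect_scale = effect_scale, n_stim = n_stim,
         photometry_rate = photometry_rate, eeg_rate = eeg_rate,
         scored = scored, metric = metric),
    class = "fp_plan"
  )
}

# metric windows per sensor/anchor; smoothing windows are expressed in
# seconds (0.1 s display filter / 0.5 s quantification smoothing, i.e. the
# 100- and 500-point windows at 1 kHz) and converted to points at `rate`
metric_spec_for <- function(sensor, anchor, rate) {
  smooth_points <- max(1L, round(0.5 * rate))
  if (sensor == "lactate") {
    list(smooth_points = smooth_points, auc_window = c(0, 30),
         auc_exclusions = NULL, peak_window = c(30, 400), mode = "peak",
         phases = list(early = c(0, 30), late = c(30, 400)), ref = 100)
  } else if (anchor == "transition") {
    list(smooth_points = smooth_points, auc_window = c(0, 30),
         auc_exclusions = NULL, peak_window = c(0, 60), mode = "peak",
         ref = 0)
  } else {
    list(smooth_points = smooth_points, auc_window = c(0, 30),
         auc_exclusions = list(c(0, 1), c(30, 31)),
         peak_window = c(1, 120),
         mode = if (sensor == "Laconic") "biphasic" else "peak",
         ref = 0)
  }
}

snippet_window_for <- function(sensor, anchor) {
  if (sensor == "lactate") c(pre = 60, post = 400)
  else if (anchor == "transition") c(pre = 30, post = 60)
  else c(pre = 10, post = 120)
}

display_filter_points <- function(rate) max(1L, round(0.1 * rate))

# one stimulation session -> fp_session with metrics
quantify_stim_session <- function(rec, plan, session_id, condition) {
  sensor <- rec$metadata$sensor
  tr <- sensor_trace(rec)
  rate <- (nrow(tr) - 1) / (tr$time[nrow(tr)] - tr$time[1])
  tr$value <- moving_average(tr$value, display_filter_points(rate))
  opening <- dplyr::filter(rec$events, .data$role == "opening")
  win <- snippet_window_for(sensor, "stim")
  mode <- if (sensor == "lactate") "percent" else "delta"
  ens <- tryCatch(
    extract_snippets(tr, opening, pre = win["pre"], post = win["post"],
                     baseline_dur = 5, mode = mode),
    error = function(e) NULL
  )
  if (is.null(ens)) {
    # all events fell out of bounds: an invalid (but reported) session
    return(structure(
      list(trace = tibble(time = numeric(), mean = numeric()),
           n_events = 0L, valid = FALSE, reason = "n_events<3",
           metrics = NULL, session_id = session_id, condition = condition),
      class = "fp_session"
    ))
  }
  session_average(ens, design = "stim",
                  metric_spec = metric_spec_for(sensor, "stim", rate),
                  session_id = session_id, condition = condition)
}

# one transition-aligned session (evoked/spontaneous or drug designs)
quantify_transition_session <- function(rec, plan, session_id, condition,
                                        origin = NULL, min_bout_after = 30) {
  sensor <- rec$metadata$sensor
  seconds <- session_state_labels(rec, plan)
  stim_onsets <- dplyr::filter(rec$events, .data$role == "opening")$onset
  trans <- detect_transitions(seconds, "nrem", "wake",
                              min_bout_after = min_bout_after,
                              stim_onsets = stim_onsets)
  if (!is.null(origin)) trans <- dplyr::filter(trans, .data$origin == !!origin)
  cond_label <- if (is.null(origin)) condition else origin
  if (nrow(trans) == 0) {
    return(structure(
      list(trace = tibble(time = numeric(), mean = numeric()),
           n_events = 0L, valid = FALSE, reason = "n_events<1",
           metrics = NULL, session_id = session_id, condition = cond_label),
      class = "fp_session"
    ))
  }
  tr <- sensor_trace(rec)
  rate <- (nrow(tr) - 1) / (tr$time[nrow(tr)] - tr$time[1])
  tr$value <- moving_average(tr$value, display_filter_points(rate))
  win <- snippet_window_for(sensor, "transition")
  ens <- extract_snippets(tr, tibble(onset = trans$time),
                          pre = win["pre"], post = win["post"],
                          baseline_dur = 5, mode = "delta")
  session_average(ens, design = "transition",
                  metric_spec = metric_spec_for(sensor, "transition", rate),
                  session_id = session_id, condition = cond_label)
}

session_state_labels <- function(rec, plan) {
  if (isTRUE(plan$scored)) {
    hyp <- score_sleep(rec)
    refine_to_seconds(hyp)
  } else {
    attr(rec, "ground_truth")$hypnogram$seconds
  }
}

session_seed <- function(seed, i, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + i * 37L + offset
}

base_config_for <- function(plan, seed, ...) {
  sim_config(seed = seed, photometry_rate = plan$photometry_rate,
             eeg_rate = plan$eeg_rate, emg_rate = plan$eeg_rate, ...)
}

#' Run an analysis plan end to end
#'
#' Simulates every session of the plan, quantifies the event-aligned
#' responses, applies the plan's statistical comparison, and (optionally)
#' writes metric/stat/trace CSVs plus a JSON run manifest. Deterministic
#' for a fixed `(plan, seed)`.
#'
#' @param plan An [analysis_plan()].
#' @param seed Integer master seed; per-session seeds derive from it.
#' @param out_dir Output directory (or `NULL` to skip writing).
#' @return List of class `fp_run`: `metrics` (per-session tibble), `stats`
#'   (tidy test table), `tests` (list of `fp_stat`), `groups` (group
#'   averages per condition), `manifest`.
#' @export
run_pipeline <- function(plan, seed = 1, out_dir = NULL) {
  stopifnot(inherits(plan, "fp_plan"))
  res <- switch(plan$design,
    stim_vs_control = run_two_condition(plan, seed,
      conditions = c("Opt", "Ctrl"),
      config_fn = function(cfg, cond) {
        if (cond == "Ctrl") cfg$stim$control <- TRUE
        cfg
      }),
    pre_vs_drug = run_two_condition(plan, seed,
      conditions = c("Pre", "Drug"),
      config_fn = function(cfg, cond) {
        if (cond == "Drug") {
          cfg$response_params[[plan$sensor]]$amplitude <-
            cfg$response_params[[plan$sensor]]$amplitude * plan$effect_scale
        }
        cfg
      }),
    state_comparison = run_state_comparison(plan, seed),
    evoked_vs_spontaneous = run_evoked_vs_spontaneous(plan, seed),
    transition_saline_vs_cno = run_saline_cno(plan, seed)
  )
  res$manifest <- list(
    package = "sleepfp",
    version = as.character(utils::packageVersion("sleepfp")),
    design = plan$design, sensor = plan$sensor, seed = seed,
    plan_hash = rlang::hash(plan),
    timestamp = NULL
  )
  class(res) <- "fp_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

run_two_condition <- function(plan, seed, conditions, config_fn) {
  sessions <- list()
  for (i in seq_len(plan$n_sessions)) {
    for (j in seq_along(conditions)) {
      cond <- conditions[j]
      cfg <- base_config_for(plan, seed = session_seed(seed, i, j),
                             duration = plan$duration)
      cfg$stim$n_per_session <- plan$n_stim
      if (plan$sensor == "lactate") cfg$stim$min_interval <- 420
      cfg <- config_fn(cfg, cond)
      rec <- simulate_recording(cfg, sensor = plan$sensor,
                                with_eeg = isTRUE(plan$scored))
      sessions[[length(sessions) + 1L]] <-
        quantify_stim_session(rec, plan, session_id = paste0("m", i),
                              condition = cond)
    }
  }
  finish_paired(plan, sessions, conditions)
}

run_state_comparison <- function(plan, seed) {
  sessions <- list()
  for (i in seq_len(plan$n_sessions)) {
    for (s in STATES) {
      dur <- if (s == "rem") plan$rem_duration else plan$duration
      cfg <- base_config_for(plan, seed = session_seed(seed, i, match(s, STATES)),
                             duration = dur)
      cfg$stim$n_per_session <- plan$n_stim
      cfg$stim$target_state <- s
      rec <- suppressWarnings(
        simulate_recording(cfg, sensor = plan$sensor,
                           with_eeg = isTRUE(plan$scored))
      )
      if (nrow(rec$events) == 0) next
      sessions[[length(sessions) + 1L]] <-
        quantify_stim_session(rec, plan, session_id = paste0("m", i),
                              condition = s)
    }
  }
  metrics <- purrr::map_dfr(sessions, tidy)
  vm <- dplyr::filter(metrics, .data$valid)
  groups_list <- split(vm[[plan$metric]], vm$condition)[STATES]
  groups_list <- purrr::compact(groups_list)
  tests <- list()
  # Friedman across states on sessions with all three states valid
  wide <- vm |>
    dplyr::select("session_id", "condition", dplyr::all_of(plan$metric)) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = dplyr::all_of(plan$metric))
  complete <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(complete) >= 2 && all(STATES %in% names(complete))) {
    tests$friedman <- friedman_rank(as.matrix(complete[, STATES]))
  }
  if (length(groups_list) >= 2 && all(lengths(groups_list) >= 2)) {
    tests$steel_dwass <- steel_dwass(groups_list)
  }
  list(metrics = metrics, tests = tests,
       stats = purrr::map_dfr(tests, tidy),
       groups = group_averages_by_condition(sessions))
}

run_evoked_vs_spontaneous <- function(plan, seed) {
  sessions <- list()
  for (i in seq_len(plan$n_sessions)) {
    cfg <- base_config_for(plan, seed = session_seed(seed, i, 0L),
                           duration = plan$duration,
                           respond_transitions = TRUE)
    cfg$stim$n_per_session <- plan$n_stim
    cfg$stim$induce_awakening <- TRUE
    rec <- simulate_recording(cfg, sensor = plan$sensor,
                              with_eeg = isTRUE(plan$scored))
    for (orig in c("evoked", "spontaneous")) {
      sessions[[length(sessions) + 1L]] <-
        quantify_transition_session(rec, plan, session_id = paste0("m", i),
                                    condition = orig, origin = orig)
    }
  }
  finish_paired(plan, sessions, c("evoked", "spontaneous"))
}

run_saline_cno <- function(plan, seed) {
  sessions <- list()
  for (i in seq_len(plan$n_sessions)) {
    for (j in 1:2) {
      cond <- c("saline", "CNO")[j]
      cfg <- base_config_for(plan, seed = session_seed(seed, i, 10L + j),
                             duration = plan$duration,
                             respond_transitions = TRUE)
      if (cond == "CNO") {
        cfg$transition_response$amplitude <-
          cfg$transition_response$amplitude * plan$effect_scale
      }
      cfg$stim$n_per_session <- 0L
      rec <- simulate_recording(cfg, sensor = plan$sensor,
                                with_eeg = isTRUE(plan$scored))
      sessions[[length(sessions) + 1L]] <-
        quantify_transition_session(rec, plan, session_id = paste0("m", i),
                                    condition = cond)
    }
  }
  finish_paired(plan, sessions, c("saline", "CNO"))
}

finish_paired <- function(plan, sessions, conditions) {
  metrics <- purrr::map_dfr(sessions, tidy)
  vm <- dplyr::filter(metrics, .data$valid)
  tests <- list()
  if (all(conditions %in% vm$condition)) {
    pr <- tryCatch(
      pair_conditions(vm, conditions[1], conditions[2],
                      pairing_key = "session_id", metric = plan$metric),
      error = function(e) NULL
    )
    if (!is.null(pr) && length(pr$a) >= 3) {
      tests$wilcoxon <- wilcoxon_signed_rank(pr$a, pr$b)
    }
  }
  list(metrics = metrics, tests = tests,
       stats = purrr::map_dfr(tests, tidy),
       groups = group_averages_by_condition(sessions))
}

group_averages_by_condition <- function(sessions) {
  conds <- unique(vapply(sessions, function(s) s$condition, character(1)))
  out <- list()
  for (cond in conds) {
    sub <- purrr::keep(sessions, ~ identical(.x$condition, cond))
    g <- tryCatch(group_average(sub), error = function(e) NULL)
    if (!is.null(g)) out[[cond]] <- g
  }
  out
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$metrics, file.path(out_dir, "metrics.csv"))
  if (nrow(res$stats %||% tibble()) > 0) {
    readr::write_csv(res$stats, file.path(out_dir, "stats.csv"))
  }
  for (cond in names(res$groups)) {
    readr::write_csv(res$groups[[cond]]$trace,
                     file.path(out_dir, paste0("group_trace_", cond, ".csv")))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fp_run <- function(x, ...) {
  cat(sprintf("<fp_run> %s | %d session rows\n",
              x$manifest$design, nrow(x$metrics)))
  if (!is.null(x$stats) && nrow(x$stats) > 0) print(x$stats)
  invisible(x)
}
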