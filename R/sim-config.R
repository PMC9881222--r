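#' Simulation configuration for synthetic recordings
#'
#' Bundles every parameter of the synthetic-recording generator: sleep
#' architecture, EEG/EMG spectral structure, stimulation protocol, and the
#' state-conditioned sensor response kernels. Defaults describe a head-fixed
#' mouse recorded during the light phase: exponential state bouts (wake
#' 150 s, NREM 120 s, REM 60 s, REM entered only from NREM), 1-kHz EEG/EMG
#' and photometry, 1-Hz amperometric lactate, and an optogenetic protocol of
#' 3-7 stimulations per session at >= 5-min intervals (1-s blue light, then
#' 1-s yellow light 30 s later).
#'
#' @param seed Integer seed; every random draw in the generator derives from
#'   it through deterministic sub-streams, so identical configs give
#'   bit-identical recordings.
#' @param duration Recording length in seconds.
#' @param state_dwell_means Named numeric, mean bout length (s) per state
#'   (`wake`, `nrem`, `rem`). A zero mean removes the state entirely.
#' @param rem_entry_prob Probability that a NREM bout is followed by REM
#'   rather than wake (REM is never entered from wake).
#' @param min_bout Minimum bout length in seconds.
#' @param eeg_rate,emg_rate,photometry_rate Sampling rates in Hz (1000 by
#'   default, matching 1-kHz acquisition).
#' @param lactate_rate Sampling rate of the amperometric lactate channel (Hz).
#' @param band_powers Per-state relative amplitudes of the delta (0.5-4 Hz),
#'   theta (6-9 Hz) and broadband EEG components.
#' @param emg_levels Per-state standard deviation of the band-passed EMG
#'   (arbitrary uV): high in wake, low in NREM, atonia in REM.
#' @param emg_bursts List: `n_micro` bursts injected into NREM
#'   (micro-awakenings), `n_active` into wake (active-awake onsets), each of
#'   `duration` s at `gain` times the local state amplitude.
#' @param response_params Per-sensor list of state-conditioned response
#'   kernels. Each entry has `amplitude` (named per state; dR/R for FRET
#'   ratios, dF/F for single-channel), `latency`, `rise_tau`, `decay_tau`
#'   (seconds) of the difference-of-exponentials kernel.
#' @param trough_params Laconic-only initial trough: `depth` (dR/R),
#'   `latency`, `rise_tau`, `trough_tau` (decay) in seconds.
#' @param lactate_kernel Bimodal extracellular-lactate kernel (percent of
#'   baseline): fast `early_amp`/`early_rise`/`early_tau` component during
#'   stimulation and a slow `late_amp` component starting `late_delay` s
#'   after onset.
#' @param transition_response Sensor kernel injected at spontaneous
#'   NREM-to-wake transitions (used by transition-aligned designs).
#' @param respond_transitions Logical; inject `transition_response` kernels
#'   at NREM-to-wake transitions (off by default; stimulation designs only
#'   carry stimulation-locked responses).
#' @param bleach_tau Photobleaching time constant (s) of the fluorescence
#'   baseline.
#' @param drift_sd Relative amplitude of the slow additive baseline drift.
#' @param noise_sd Named numeric: `photometry` is the per-sample SD of the
#'   ratio-equivalent Gaussian noise (dR/R units), `lactate` the per-sample
#'   SD in percent of baseline.
#' @param stim Stimulation protocol list: `n_per_session` (3-7),
#'   `min_interval` (s, >= 300; >= 420 is enforced for lactate protocols),
#'   `target_state`, `blue_dur`, `yellow_offset`, `yellow_dur`, `settle`
#'   (s the animal must already be in the target state), `control`
#'   (yellow light in place of blue), `induce_awakening` (stimulations in
#'   NREM wake the animal after `wake_latency` s for about `evoked_bout` s).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration = 7200,
                       state_dwell_means = c(wake = 150, nrem = 120, rem = 60),
                       rem_entry_prob = 0.35,
                       min_bout = 4,
                       eeg_rate = 1000, emg_rate = 1000,
                       photometry_rate = 1000, lactate_rate = 1,
                       band_powers = list(
                         wake = c(delta = 1, theta = 1, broad = 1.5),
                         nrem = c(delta = 4, theta = 0.6, broad = 0.8),
                         rem  = c(delta = 0.5, theta = 2.5, broad = 0.5)
                       ),
                       emg_levels = c(wake = 30, nrem = 8, rem = 3),
                       emg_bursts = list(n_micro = 0, n_active = 0,
                                         gain = 10, duration = 2),
                       response_params = list(
                         ATeam = list(
                           amplitude = c(wake = 0.005, nrem = 0.010, rem = 0.015),
                           latency = 1, rise_tau = 5, decay_tau = 40
                         ),
                         Laconic = list(
                           amplitude = c(wake = 0.004, nrem = 0.010, rem = 0.010),
                           latency = 25, rise_tau = 10, decay_tau = 60
                         ),
                         single = list(
                           amplitude = c(wake = 0.02, nrem = 0.05, rem = 0.05),
                           latency = 1, rise_tau = 3, decay_tau = 20
                         )
                       ),
                       trough_params = list(depth = 0.008, latency = 0.5,
                                            rise_tau = 1.5, trough_tau = 8),
                       lactate_kernel = list(early_amp = 5, early_rise = 5,
                                             early_tau = 20, latency = 2,
                                             late_amp = 10, late_delay = 60,
                                             late_rise = 30, late_tau = 120),
                       transition_response = list(amplitude = 0.008,
                                                  latency = 0.5,
                                                  rise_tau = 5, decay_tau = 40),
                       respond_transitions = FALSE,
                       bleach_tau = 2e4,
                       drift_sd = 5e-4,
                       noise_sd = c(photometry = 0.002, lactate = 0.5),
                       stim = list(n_per_session = 5, min_interval = 300,
                                   target_state = "nrem", blue_dur = 1,
                                   yellow_offset = 30, yellow_dur = 1,
                                   settle = 10, control = FALSE,
                                   induce_awakening = FALSE,
                                   wake_latency = 5, evoked_bout = 60)) {
  cfg <- list(
    seed = as.integer(seed), duration = duration,
    state_dwell_means = state_dwell_means, rem_entry_prob = rem_entry_prob,
    min_bout = min_bout,
    eeg_rate = eeg_rate, emg_rate = emg_rate,
    photometry_rate = photometry_rate, lactate_rate = lactate_rate,
    band_powers = band_powers, emg_levels = emg_levels,
    emg_bursts = emg_bursts,
    response_params = response_params, trough_params = trough_params,
    lactate_kernel = lactate_kernel,
    transition_response = transition_response,
    respond_transitions = respond_transitions,
    bleach_tau = bleach_tau, drift_sd = drift_sd, noise_sd = noise_sd,
    stim = stim
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_scalar_pos(cfg$duration, "duration")
  for (r in c("eeg_rate", "emg_rate", "photometry_rate", "lactate_rate")) {
    assert_scalar_pos(cfg[[r]], r)
  }
  dm <- cfg$state_dwell_means
  if (is.null(names(dm)) || !all(names(dm) %in% STATES)) {
    abort("`state_dwell_means` must be named with states wake/nrem/rem")
  }
  if (any(!is.finite(dm)) || any(dm < 0)) {
    abort("state dwell means must be finite and >= 0")
  }
  if (all(dm == 0)) abort("at least one state dwell mean must be positive")
  if (cfg$stim$min_interval < 0) abort("stim$min_interval must be >= 0")
  if (!cfg$stim$target_state %in% STATES) {
    abort("stim$target_state must be one of wake/nrem/rem")
  }
  amps <- unlist(lapply(cfg$response_params, function(p) p$amplitude))
  if (any(!is.finite(amps))) abort("response amplitudes must be finite")
  if (any(unlist(cfg$noise_sd) < 0)) abort("noise_sd values must be >= 0")
  if (cfg$bleach_tau <= 0) abort("bleach_tau must be positive")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d, duration %g s\n", x$seed, x$duration))
  cat(sprintf("  dwell means: %s\n",
              paste(sprintf("%s %g s", names(x$state_dwell_means),
                            x$state_dwell_means), collapse = ", ")))
  cat(sprintf("  rates: eeg %g, emg %g, photometry %g, lactate %g Hz\n",
              x$eeg_rate, x$emg_rate, x$photometry_rate, x$lactate_rate))
  cat(sprintf("  stim: %d per session, >=%g s apart, target %s%s\n",
              x$stim$n_per_session, x$stim$min_interval,
              x$stim$target_state,
              if (isTRUE(x$stim$control)) " (control light)" else ""))
  invisible(x)
}
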