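# sleepfp

Event-triggered analysis of state-dependent fiber-photometry and biosensor
recordings in behaving rodents.

Fluorescent biosensors read out through an implanted optical fiber — FRET
ratio sensors for ATP (ATeam, ratio R = mVenus/CFP) and lactate (Laconic,
R = CFP/mVenus), intensity sensors (GRAB, GCaMP, PinkFlamindo, ΔF/F), and
1-Hz amperometric extracellular lactate — respond to optogenetic
stimulation with amplitudes that depend on the animal's vigilance state.
Quantifying those responses requires a full stack: score sleep from
EEG/EMG, align signals to stimulations and state transitions, normalize to
pre-event baselines, extract AUC/peak/trough metrics under the study's
session rules, and compare conditions with small-sample nonparametric
tests. `sleepfp` implements that stack as a tidyverse-style R package, plus
a seeded synthetic-recording generator with ground-truth annotations so
every stage is testable without any raw data.

## What it computes

* **Sleep scoring** — 4-s epochs from Welch band powers (delta 0.5–4 Hz,
  theta 6–9 Hz) and EMG RMS via the conventional decision tree
  (EMG ⇒ wake; theta/delta ⇒ REM; else NREM), refined to 1-s labels;
  NREM→wake transition detection (spontaneous awakenings require ≥ 30 s of
  wake; stimulation-proximal transitions are flagged evoked); EMG-threshold
  (mean + 10·SD) micro-awakening and active-awake onset detection.
* **Photometry quantification** — ΔR/R = (R − R₀)/R₀ with R₀ the 5-s
  pre-event mean (percent-of-baseline for lactate), 0.1-s display filter
  and 0.5-s quantification smoothing, trapezoidal AUC over the 30-s
  stimulation window minus 1-s illumination exclusions (effective
  [1, 30), i.e. a constant c integrates to 29 c), early/late lactate
  phases (0–30 / 30–400 s), peak/trough extraction including the biphasic
  trough-then-peak mode, and signed AUC splitting.
* **Session rules** — stimulation sessions valid with ≥ 3 stimulations,
  transition sessions with ≥ 1 event per 30-min measurement; sessions are
  the statistical unit; group traces are mean ± SEM across session means.
* **Statistics** — exact two-sided Wilcoxon signed-rank (full 2ⁿ sign
  enumeration, n ≤ 15) and Mann–Whitney U (full arrangement enumeration,
  N ≤ 16), Friedman and Kruskal–Wallis, and the Steel–Dwass (all-pairs,
  studentized-range reference) and Steel (many-to-one, equicorrelated
  ρ = 0.5 maximum via quadrature) post-hoc procedures, with broom-style
  `tidy()`/`glance()` methods.
* **Pipelines** — `run_pipeline()` reproduces the standard comparison
  designs on synthetic data: stimulation vs yellow-light control, pre vs
  drug, wake/NREM/REM state comparison, evoked vs spontaneous awakening,
  and saline vs CNO transition analysis.

## Worked example

Simulate one stimulation session (NREM-targeted, five 1-s blue + yellow
light pairs ≥ 5 min apart), score it, and quantify the ATP response:

```r
library(sleepfp)
library(dplyr)

cfg <- sim_config(seed = 42, duration = 3600,
                  eeg_rate = 200, emg_rate = 200, photometry_rate = 100)
rec <- simulate_recording(cfg, sensor = "ATeam")
rec
#> <fp_recording> 3600.0 s, 4 channel(s), 10 event(s)
#>   eeg      eeg             200 Hz  720000 samples [uV]
#>   emg      emg             200 Hz  720000 samples [uV]
#>   mVenus   fluorescence    100 Hz  360000 samples [a.u.]
#>   CFP      fluorescence    100 Hz  360000 samples [a.u.]

score_sleep(rec)
#> <fp_hypnogram> 900 epochs of 4 s
#> # A tibble: 3 × 2
#>   state     n
#>   <chr> <int>
#> 1 nrem    331
#> 2 rem      64
#> 3 wake    505

tr <- sensor_trace(rec) |> mutate(value = moving_average(value, 10))
ens <- extract_snippets(tr, filter(rec$events, role == "opening"),
                        pre = 10, post = 120, baseline_dur = 5,
                        mode = "delta")
ses <- session_average(ens, design = "stim",
                       metric_spec = list(smooth_points = 50,
                                          auc_window = c(0, 30),
                                          auc_exclusions = list(c(0, 1), c(30, 31)),
                                          peak_window = c(1, 120),
                                          mode = "peak"),
                       session_id = "m1", condition = "Opt")
tidy(ses)
#> # A tibble: 1 × 10
#>   session_id condition n_events valid reason   auc peak_value peak_time
#>   <chr>      <chr>        <int> <lgl> <chr>  <dbl>      <dbl>     <dbl>
#> 1 m1         Opt              5 TRUE  <NA>   0.242     0.0103      14.1
```

The five NREM stimulations were injected with a 1.0% ΔR/R kernel: the
session-mean peak comes back as 0.0103 ΔR/R (1.03%) at 14.1 s after blue
onset, with a stimulation AUC of 0.242 (ΔR/R)·s over the effective
[1, 30) s window. `autoplot(ens)` shows the per-event snippets and their
mean; group-level traces come from `group_average()` and the comparison
designs from `run_pipeline(analysis_plan("state_comparison"), seed = 1)`.

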