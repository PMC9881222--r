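---
title: "State-dependent fiber-photometry analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent fiber-photometry analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepfp)
```

`sleepfp` analyses fluorescent-biosensor and amperometric recordings from
behaving rodents whose responses depend on vigilance state: FRET sensors
read out as a channel ratio (mVenus/CFP for the ATP sensor ATeam, the
inverted CFP/mVenus for the lactate sensor Laconic), intensity sensors
(GRAB, GCaMP, PinkFlamindo) as a single fluorescence channel, and
extracellular lactate as a 1-Hz amperometric current. The package covers
the full path from raw channels to statistics: sleep scoring from EEG/EMG,
event-triggered normalization and quantification, session and group
averaging under study-design validity rules, and nonparametric tests. A
seeded synthetic-recording generator with ground-truth annotations makes
each stage testable end to end.

## Signal model and normalization

Raw sensor channels are modelled (and, in the generator, synthesized) as

\[ F_c(t) = B_c \, e^{-t/\tau_{bleach}} \, (1 + d(t)) \, (1 + s_c(t)) \,
   (1 + \varepsilon_c(t)), \]

with channel baseline \(B_c\), slow additive drift \(d(t)\), the
event-evoked fractional response \(s_c(t)\) and white Gaussian noise
\(\varepsilon_c\). Quantification never works on raw channels directly:

1. the ratio \(R = F_{num}/F_{den}\) (or single-channel \(F\)) is filtered
   with a centered moving average (0.1 s — 100 points at 1 kHz);
2. each event-aligned snippet is normalized to its own pre-event baseline:
   \(\Delta R/R = (R - R_0)/R_0\) with \(R_0\) the mean over the 5 s just
   before the event (4 s — one scoring epoch — for sub-state onsets, which
   use a zero-point shift instead of a ratio); extracellular lactate is
   expressed as percent of the 5-s pre-event mean;
3. session means are smoothed with a 0.5-s moving average (500 points at
   1 kHz) before metric extraction.

The delta-mode baseline identity — the normalized snippet averages to
exactly zero over its own baseline window — is algebraically exact and is
asserted to 1e-12 in the tests.

Metrics are the field's standard ones. The stimulation AUC integrates
\(\Delta R/R\) (trapezoidal rule at native sampling) over the 30-s
illumination window, excluding 1 s at each light exposure; exclusions are
implemented as "integral over the window minus integral over each excluded
sub-interval", so the constant-trace value over the effective
\([1, 30)\) window is exactly amplitude × 29 s. Extracellular lactate is
quantified in an early phase (0–30 s, during illumination) and a late phase
(30–400 s, after it). Peak and trough searches run on the smoothed trace;
the biphasic (Laconic-style trough-then-rise) mode first finds the global
maximum, then the trough before it, then re-searches the peak after the
trough, guaranteeing `trough_time < peak_time`. Ties break toward the
earliest time; flat traces are reported with a warning rather than an
error.

### Default analysis windows

| quantity | window | notes |
|---|---|---|
| stimulation AUC | 0–30 s, minus [0,1) and [30,31) | illumination artifact exclusion |
| fluorescence peak | 1–120 s | config-overridable |
| lactate phases | 0–30 s / 30–400 s | early / late |
| lactate late peak | 30–400 s | |
| transition-aligned peak | 0–60 s | snippet −30 to +60 s |
| sub-state snippets | −8 to +20 s | baseline 4 s, zero-point shift |

The peak-search windows are design choices (the source protocols display
but do not tabulate them); every window is an explicit argument.

## Sleep scoring

EEG/EMG are scored in 4-s epochs. Per epoch we compute delta (0.5–4 Hz)
and theta (6–9 Hz) band power from a Hann-windowed periodogram whose
segment equals the epoch (the degenerate single-segment Welch estimate),
plus the RMS of the 10–100 Hz band-passed EMG. Band filtering is done by
FFT masking, which stays numerically stable for a 0.5-Hz edge at a 1-kHz
rate where low-order IIR designs do not. Classification is the
conventional decision tree: high EMG ⇒ wake; otherwise theta/delta above 1
⇒ REM, else NREM. The EMG threshold defaults to a deterministic two-class
(Otsu) split of the log epoch EMG RMS — this presumes both wake and sleep
occur in the recording; single-state recordings should pass an explicit
threshold. Optional smoothing removes isolated one-epoch REM calls inside
wake; epochs with non-finite features are flagged unscorable and inherit
the previous label.

Epoch labels are then re-expressed at 1-s resolution. Plain expansion
replicates each epoch label four times; an optional refinement pass moves a
wake onset earlier within the preceding epoch to the first second whose
EMG metric crosses the wake threshold. Both behaviours are provided
because second-level rescoring of 4-s scores can be defined either way;
refinement never moves a boundary by more than one epoch and never changes
which states are present.

Transitions are detected on the 1-s labels: a NREM→wake transition counts
as a spontaneous awakening only if the wake bout lasts at least 30 s;
transitions with a stimulation onset within the preceding 35 s (the 30-s
illumination plus latency margin) are flagged evoked. Sub-state onsets
(micro-awakenings in NREM, active-awake onsets in wake) use a per-second
EMG RMS threshold estimated within the parent state. The threshold phrase
"mean greater than k times the SD" is read as `mean + k·SD` (k = 10); the
alternative `k·SD` reading is one flag away (`rule = "k_sd"`). Distinct
onsets must be 8 s (two epochs) apart; at least 60 s of parent state is
required to estimate the threshold.

## Session and group rules

The session is the unit of statistical analysis. A stimulation session is
valid with ≥ 3 stimulations (the protocol's lower bound; a strict
"more than 3" reading is `min_events = 4`); a transition session is a
30-min measurement with ≥ 1 event. Invalid sessions are returned flagged
with a reason and excluded from group averages and group `n` — never
silently dropped. Group traces report mean ± SEM across session means;
paired designs align per-session metrics by subject and report unpaired
keys.

## Nonparametric statistics

Two-sample comparisons use the two-sided Wilcoxon signed-rank test (paired)
or Mann–Whitney U (unpaired). Both are exact by default in small samples:
the signed-rank null is enumerated over all \(2^n\) sign assignments of the
mid-ranked absolute differences (zeros dropped by Wilcoxon's rule; Pratt's
method by flag) for n ≤ 15, and the U null over all
\(\binom{n_a+n_b}{n_a}\) arrangements of the pooled observed values for
\(n_a+n_b \le 16\) — enumerating arrangements of the observed values makes
the exact path valid under ties too. The cutoffs keep each call well under
a second; larger samples fall back to tie-corrected normal approximations
with continuity correction. Exactness is verified against independent
enumeration oracles and against `wilcox.test` in the tests.

Omnibus tests (Friedman for complete blocks, Kruskal–Wallis for
independent groups) wrap the base-R tie-corrected chi-square
implementations. Post-hoc procedures are authored here:

* **Steel–Dwass (all pairs)** — each pair's rank-sum statistic is
  standardized under the null and \(\sqrt 2\,|z|\) is referred to the
  studentized-range distribution with k groups and infinite df.
* **Steel (many-to-one)** — each treatment-vs-control \(|z|\) is referred
  to the maximum of \(k-1\) equicorrelated (ρ = 0.5) standard normals.
  Writing the correlated normals as \(Z_j = (W + E_j)/\sqrt 2\) with a
  shared \(W\) reduces that maximum probability to a one-dimensional
  integral over \(W\), which `stats::integrate` evaluates to ~1e-10 —
  deterministic and faster than Monte-Carlo sampling, which is kept as the
  independent oracle in the test suite (agreement within Monte-Carlo
  tolerance).

A note on attained levels: with n = 10 per group the rank-sum statistic is
discrete, so the asymptotic Steel–Dwass is mildly conservative — the
per-pair attained two-sided level at the 5% family critical value is
0.0185 rather than the continuous-approximation value, and the familywise
error lands just below 0.04. The error-control simulation in the test
suite measures exactly this.

Multiple endpoints (AUC, peak value, peak time) are tested separately
without cross-endpoint correction, mirroring common reporting practice in
this field.

## The synthetic-data generator

The generator emulates what the analysis assumes, with every parameter in
one `sim_config()` object and all randomness derived from one seed through
deterministic per-channel sub-streams (identical configs give bit-identical
recordings):

* **Sleep architecture** — a semi-Markov chain with exponential bouts
  (means: wake 150 s, NREM 120 s, REM 60 s; minimum bout 4 s — one scoring
  epoch), REM entered only from NREM (probability 0.35), yielding a
  realistic ~7% REM fraction for a mouse in the light phase.
* **EEG/EMG** — band-limited Gaussian components with state-dependent
  weights (NREM delta-dominant, REM theta-dominant, wake intermediate with
  high EMG); EMG amplitude per state (wake ≫ NREM > REM atonia); optional
  injected EMG bursts at 10× local amplitude, logged as ground truth.
* **Stimulation protocol** — 1-s blue light, then 1-s yellow light 30 s
  later; 3–7 stimulations per session at ≥ 5-min intervals (≥ 7 min for
  lactate protocols, enforced); onsets gated on the true hypnogram after a
  10-s settling time, emulating online visual state judgment. Control
  sessions use yellow light in place of blue and evoke no response.
* **Responses** — a difference-of-exponentials kernel
  \(A(e^{-t/\tau_d} - e^{-t/\tau_r})\), delayed by a latency and scaled so
  its maximum is the state-conditioned amplitude. Defaults for the ATP
  sensor: wake 0.5%, NREM 1.0%, REM 1.5% ΔR/R with per-sample ratio noise
  SD 0.2%. Laconic adds a negative early trough kernel (biphasic);
  extracellular lactate uses a bimodal early + delayed-late kernel whose
  late peak falls inside the 30–400 s window. FRET responses are split
  anti-correlated: the numerator channel carries +60% of the ratio change
  and the denominator −40% (the split is arbitrary but recorded), so the
  ratio carries the injected kernel to first order.
* **Couplings for transition designs** — optionally, stimulations in NREM
  wake the animal ~5 s after onset (evoked awakenings) and NREM→wake
  transitions carry their own response kernel, which chemogenetic
  (CNO-style) conditions scale down.

What the generator does **not** emulate: motion and hemodynamic artifacts
beyond additive drift, non-exponential bout-length distributions,
inter-individual variability in spectra, sensor saturation, and any
biophysical kinetics of the underlying neurotransmitter/metabolite
cascade. Passing tests therefore demonstrate correctness of the analysis
logic under the stated statistical structure, not robustness to every
artifact of real recordings.

## Numerical choices

* Moving averages are centered with truncated edges (length-preserving,
  exact on constants); window widths are given in points, and the
  pipeline converts the 0.1-s/0.5-s conventions using the channel rate.
* AUC uses the trapezoidal rule at native sampling; exclusion intervals
  are subtracted as sub-integrals, so zero-width overlaps contribute
  nothing and the effective integration domain is a closed set difference.
* The yellow-light exclusion [30, 31) s only matters when the analysis
  window extends beyond 30 s; with the default window it merely removes
  the boundary point.
* Ratio denominators must exceed 1e-6 × their median; the first offending
  index is named in the error.
* Per-stream seeds are derived affinely from the master seed and stay
  below 2^31.

## Problem sizes in the shipped tests

The test suite and the acceptance script run the generator at reduced
rates — EEG/EMG 200 Hz, photometry 100 Hz (full-fidelity 1 kHz remains the
package default) — with the smoothing windows scaled in seconds. Scoring
recovery uses a 2-h recording; response-recovery checks use 100 replicate
five-session experiments (three per-state recordings per session, REM
recordings longer because REM bouts are scarce); error-control simulations
use 20,000 synthetic families. These sizes were chosen so the whole suite
completes in minutes on one CPU while leaving each check statistically
well-powered.

## Known limitations

* The scorer is a fixed-threshold decision tree, not a learned classifier;
  its auto-calibration assumes wake and sleep both occur in the recording.
* Steel/Steel–Dwass use asymptotic references (with the quadrature-exact
  equicorrelated maximum for Steel); exact permutation versions are not
  implemented.
* EDF export is minimal (16-bit, 1-s records, uniform rate across the
  channels of one file) — sufficient for polysomnography interchange, not
  a general EDF+ implementation.
* No isosbestic-channel motion correction and no photobleaching
  detrending beyond per-event baseline normalization: the event-aligned
  designs make both unnecessary for the quantities computed here.
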