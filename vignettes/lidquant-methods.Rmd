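---
title: "Quantifying dyskinesia progression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyskinesia progression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidquant)
```

lidquant quantifies how levodopa-induced dyskinesia (LID) evolves over
repeated levodopa treatment in the 6-OHDA mouse model of Parkinson's
disease, from four kinds of recordings: two-channel fiber photometry of
striatal medium spiny neurons (MSNs), abnormal involuntary movement (AIM)
scores and open-field velocity, in vivo single-unit spike trains, and ex
vivo whole-cell recordings. Every analysis stage has a seeded synthetic
generator with known ground truth, so the full pipeline is testable
without animal data. This vignette explains the models behind each stage,
the parameters that matter, and the design decisions taken where the
procedures were genuinely open.

All times are stored in seconds with t = 0 at the levodopa injection and
the 30-minute baseline at negative times; 1-minute bins are half-open
[k, k+1). Two windows recur throughout: **LID onset**, the first 20
minutes post-injection, and **LID offset**, 30–90 minutes post-injection.

## Photometry

The raw recording has a 465 nm signal channel and a 405 nm isosbestic
channel that shares motion and autofluorescence artifacts but carries no
calcium signal. Processing follows the standard sequence:

1. **Motion correction.** The 405 nm channel is mapped onto the 465 nm
   channel by ordinary least squares over the whole session and the fitted
   control is subtracted. If the isosbestic channel is constant the fit
   degenerates to intercept-only (with a warning).
2. **Bleach normalization.** A single decaying exponential plus offset is
   fit (Levenberg–Marquardt) to the 465 nm channel and used as the
   baseline-fluorescence reference F(t). ΔF/F% = 100 × corrected/F(t),
   i.e. the bleach-normalized signal minus one, so an artifact-free flat
   session sits at 0% and the 2% detection criterion applies directly.
   Because the least-squares isosbestic fit makes the corrected signal
   zero-mean, the reference must come from the total fluorescence rather
   than from the corrected signal itself; the two formulations are
   equivalent up to the offset that OLS removes. If the exponential fit
   fails to converge, a linear trend is used and the processing record is
   flagged. Dopamine-sensor (GRAB-DA) sessions skip bleach normalization
   and use the fitted isosbestic as reference.
3. **Smoothing.** Centered moving average, default 0.5 s, with shrinking
   windows at the edges.

The processing record (isosbestic slope/intercept, bleach parameters,
smoothing window) is stored on the trace, so the result is reproducible
from the raw channels.

**Transient detection.** Transients are valley-to-peak excursions of the
signal envelope strictly exceeding 2% ΔF/F. The default back-end takes the
local maxima of the smoothed trace as envelope peaks and pairs each peak
with the lower-envelope minimum inside a 2 s lookback window — long enough
to span a GCaMP6s-like rise (kernel rise τ ≈ 0.2 s) even when a noise
ripple interrupts it, short enough that slow drift cannot accumulate into
a spurious >2% swing. The search never reaches past the previously
detected event, so a single transient is never counted twice. A
sliding-window max/min envelope ("window") is available behind the same
config key; it is coarser and trades some sensitivity. Detection is a step
function of amplitude exactly at the threshold (strict inequality), which
the test suite verifies by bisection to 0.01%.

**Session metrics.** Events are binned per minute; the baseline rate is
the mean over [−30, 0) min, and Δrate = binned − baseline. Windowed AUC is
the bin-sum times the 1-minute width (a step-function integral — a
constant 3/min over the 20-minute onset window integrates to exactly 60).
Time-to-baseline is the first minute after the absolute peak of Δ at which
the series has crossed back to baseline (sign-aware, tolerance `tol`,
default 0) and stays there for 5 consecutive bins; sessions that never
satisfy the rule are censored at the session end and flagged, never
imputed. With Poisson counting noise and `tol = 0` this rule is strict:
sessions whose rate hovers just above baseline late in the recording are
censored, and users analyzing noisy cohorts should either widen `tol` or
treat censoring explicitly. Dopamine-sensor sessions report peak 1-minute
binned ΔF/F instead of event statistics.

**Known limitation — detector dead time.** Any envelope detector merges
events that arrive within roughly the kernel decay of each other
(~0.5–1 s here). At the default simulated rates (4/min baseline, up to
10/min at the response peak) this costs a few percent sensitivity; at much
higher rates, Δrate is systematically undercounted. The rate-recovery
calibration is therefore stated for the low-overlap regime (≤ ~5
events/min), and the sensitivity/FDR bounds (≥ 0.95 / ≤ 0.05 at amplitude
5%, noise 0.3%) are verified at the default study conditions.

## Behavior

AIM observations carry axial, limb, and orolingual scores, each an integer
0–4, summing to a total of 0–12. The dense scoring schedule is every
minute for 20 minutes post-injection, then every 5 minutes to 120; the
sparse schedule (ex vivo cohorts) is every 20 minutes for 2 h. Windowed
AUC uses the trapezoid on the observed (irregular) timestamps with linear
interpolation at window edges; where a window edge falls outside the
scored span the nearest observation is extended (so a constant timecourse
integrates to value × width), with an "anchor at zero" alternative
available. Time to resolution is the earliest scored timepoint after the
session's peak total at which the total is 0 and remains 0; otherwise the
session is censored at the last timestamp. Velocity is averaged in
half-open 1-minute bins with a partial trailing bin dropped.

## Single units

Sorted units are screened on the refractory criterion — fewer than 1% of
inter-spike intervals below 2 ms — and split into putative MSNs vs
putative interneurons by waveform peak-to-valley duration (default
threshold 0.3 ms, a conventional striatal criterion; fully configurable
and always recorded). Only putative MSNs are classified: firing rates in
1-minute bins over the 30-minute baseline are compared with the
post-injection window (10–40 min) by a two-sided Wilcoxon rank-sum test
with tie correction; p < 0.01 calls a response, with direction from the
sign of the mean difference — increases are putative D1-MSNs, decreases
putative D2-MSNs. The test is two-sided because units are split by
direction post hoc; a significant test with exactly zero mean difference
is classified as no change. The onset-window rate change (0–20 min minus
baseline, Hz) is reported separately from the classification window.

Null calibration: on 10,000 simulated stationary 3 Hz units the fraction
called responsive is ≈ 0.01, within the binomial 3σ band — the rank-sum
approximation is well calibrated for 30-vs-30 Poisson count bins.

## Ex vivo

Current-clamp sweeps yield the f–I curve (spike count, instantaneous rate
= 1/first ISI, mean rate), rheobase (smallest tested current evoking a
spike; censored-above when nothing spikes), and AP features measured on
the first spike at rheobase: threshold where dV/dt first exceeds
20 mV/ms, half-width at half amplitude between threshold and peak with
sub-sample interpolation, AHP as threshold minus the minimum 2–50 ms
after the peak (positive magnitude). Resting potential is the pre-step
mean; subthreshold steady-state deflections give input resistance by
linear fit. The slope criterion, detection level (−10 mV crossing with
dV/dt confirmation) and windows are configurable: the source procedures do
not specify them, so all defaults are this package's choices.

mEPSCs are detected on the smoothed first derivative at 4 × MAD of the
derivative noise (5 ms minimum separation); amplitude is local baseline
minus trough. Cells qualify for group analysis only with ≥ 500 detected
events, and cumulative amplitude / inter-event-interval distributions use
only the first 500 events (499 intervals). At the default noise (1.5 pA)
and amplitudes (18 ± 5 pA, ≥ 5 pA) the false-event rate on event-free
noise stays below 0.5 Hz and sensitivity exceeds 0.9 with ±2 ms matching.

GIRK dopamine responses are plateau currents (drug-window mean minus
pre-drug baseline); the D2-sensitivity index is the 1 µM / 100 µM ratio,
undefined (flagged) when the saturating response is not positive.

## Session statistics

`correlate()` is a two-sided Pearson correlation over complete
subject×session pairs (listwise deletion, counted). `compare_timepoints()`
wraps the three designs used for progression data — repeated-measures
one-way ANOVA with Tukey contrasts (via `aov`/`emmeans`), Kruskal–Wallis
with a Dunn post-hoc (omnibus via `kruskal.test`; the Dunn z on mean ranks
with tie-corrected variance and Holm adjustment is computed here because
no packaged implementation is available), and two-way repeated-measures
ANOVA with Greenhouse–Geisser correction (via `car::Anova`). Unbalanced
repeated measures are handled by listwise deletion of incomplete subjects
with the dropped ids reported.

## Synthetic sessions: what they emulate, and what they do not

The generators reproduce the statistical structure the analyses assume:
Poisson event timing with a parametric drug-response rate profile
(gamma-like rise, exponential decay, signed for D1-/D2-like responses),
GCaMP6s-like transient kernels, channel-specific exponential bleaching
toward a floor, a shared Ornstein–Uhlenbeck motion artifact, refractory
spike trains, quantized AIM curves on the real scoring schedule, leaky-RC
sweeps with parametric APs, and biexponential minis. Artifact and noise
amplitudes scale with the instantaneous bleach level, since fiber-bending
modulates collection efficiency multiplicatively and shot noise tracks
collected fluorescence. Defaults were chosen once as realistic study
conditions: 20 Hz photometry sampling, 150-minute sessions (30 baseline +
120 post), 4 transients/min baseline with a +6/min peak response,
5 ± 1.5% amplitudes, 0.3% sensor noise, 3 Hz MSN firing with ±4 Hz
modulation, 2 ms refractoriness, AIM peak 9 with 25-minute offset tau,
rheobase 150 pA with 120 MΩ input resistance, 2 Hz minis at 18 pA.
Acquisition-rate, kinetics and noise values are stand-ins where the
source procedures do not state them, and all are config-exposed.

They do **not** emulate hemodynamic or pH artifacts, sensor biophysics
(saturation, bleaching of responsivity), bursty or oscillatory spike
statistics, electrode drift, series-resistance errors, or correlated
behavioral-neural noise. Passing tests therefore demonstrate correctness
of the quantification contracts under the assumed statistical structure,
not robustness to every pathology of real recordings.

The spike generator's refractory deletion makes the realized rate of a
programmed λ exactly λ/(1+λr) (renewal with dead time r); calibration
tests use this corrected expectation rather than raw λ.

## Numerical choices and degenerate inputs

Strict ">" at the detection threshold ("exceeding"); events exactly at the
injection time belong to bin 0; bisection and half-width crossings use
linear interpolation; the exponential bleach fit falls back to a linear
trend on non-convergence (flagged); traces shorter than two envelope
extrema yield an empty event series rather than an error; empty spike
trains, zero-variance correlations, and undefined GIRK ratios raise or
flag rather than silently propagate. Deterministic tie-breaks: AIM
quantization splits the rounded total evenly with remainders to axial >
limb > orolingual.

Problem sizes used by the test and acceptance runs — 10,000 units for the
classifier null, 100 seeds for rate calibrations, 25–60 seeds for
recovery checks, single sessions for detector operating points — were
chosen so Monte-Carlo error (3σ) is small relative to the effects under
test while the whole suite stays desk-scale.
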