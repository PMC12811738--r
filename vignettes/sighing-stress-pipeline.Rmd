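---
title: "Dissecting cardiovascular responses to paced volitional sighing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting cardiovascular responses to paced volitional sighing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A volitional sigh — a deep, sharp inhalation followed by a natural exhale —
triggers a stereotyped cardiovascular chain reaction: heart rate accelerates
in phase with peak inhalation (the R-to-R interval, RRI, dips), central
vessels dilate (pulse transit time, PTT, rises), and systolic pressure peaks
two to three beats later before recovering passively over several seconds.
Pacing such sighs at fixed intervals — a 5-minute task with one sigh every
30 s, then a 5-minute task with one sigh every 15 s, after a 5-minute
baseline — loads the cardiovascular system progressively, the way a treadmill
protocol loads it in an exercise stress test.

`sighstress` implements the full analysis chain for such protocols:

1. **Simulation** (`simulate_participant()`, `simulate_cohort()`): synthetic
   ECG-like, continuous arterial pressure, and respiration channels with
   complete ground truth.
2. **Beat processing** (`detect_r_peaks()`, `detect_bp_peaks()`,
   `correct_rri_artifacts()`, `compute_ptt_series()`,
   `extract_map_series()`, `compute_rsa_events()`, ...): beat-level indices
   from the raw channels.
3. **Spectral metrics** (`resample_to_uniform()`, `welch_psd()`,
   `band_power()`): heart rate variability (HRV) and blood pressure
   variability (BPV) band powers.
4. **Model dissection** (`fit_mixed_model()`, `task_contrasts()`,
   `influence_screen()`, `dissect_all_outcomes()`): covariate-structured
   linear mixed models separating cardiac, vascular, and autonomic
   contributions to the task response.

## The simulator: what it emulates

Beat times follow the integral pulse frequency modulation convention: an
instantaneous RRI signal (ms) is integrated and a beat fires at each integer
phase crossing. The instantaneous RRI is

```
RRI(t) = mean_rri
       + rsa_gain * sin(2*pi*f_breath * (t - rsa_delay))     # RSA coupling
       + lf_osc_amplitude * sin(2*pi*lf_osc_freq * t + phi)  # ~0.1 Hz Mayer wave
       + sum over sighs of the RRI dip kernel
       + band-limited noise,
```

floored at a refractory minimum (520 ms, ~115 bpm). The RRI dip and PTT rise
kernels are Gaussian bumps centred on each sigh's inhalation peak; the
systolic pressure kernel is a gamma-shaped rise peaking `bp_lag_beats`
(2 or 3) mean beats later with an exponential recovery — the qualitative
morphology of the single-sigh response, parameterized. The pressure channel
renders one pulse per beat whose systolic peak sits exactly at
`R time + PTT(t)`; the ECG channel renders narrow Gaussian R spikes (only
R-peak timing is consumed downstream); respiration superposes an eupneic
sinusoid with asymmetric sigh boluses (fast inhale, slower exhale).

Key default parameters and the reasoning behind them:

| Parameter | Default | Why |
|---|---|---|
| `mean_rri` | 861 ms (M) / 786 ms (F) | baseline heart rates near 70 / 76 bpm, the typical sex difference in healthy young adults |
| `rsa_gain`, `rsa_delay` | 40 ms, 0.8 s | moderate vagal coupling; delay programmable so the RSA-proxy recovery can be verified |
| `lf_osc_amplitude` | 18 ms (M) / 13 ms (F) | Mayer-wave oscillation, higher LF-HRV in males |
| `rri_dip_amplitude` | 150 ms (x `response_gain`) | a sigh accelerates heart rate visibly for a few seconds |
| `ptt_rise_amplitude` | 35 ms | transient vasodilation in phase with inhalation |
| `bp_rise_amplitude`, `bp_lag_beats` | 10 mmHg, 2-3 beats | pressure peaks a few beats after peak inhalation |
| `response_gain` | 1.2 (M) / 0.85 (F) | males mount larger sympathetic responses |
| `short_rsa_mult` | 0.8 (M) / 0.6 (F) | vagal withdrawal only under the heavier 15-s load, stronger in females |
| `short_map_gain_mmhg` | 3 | stroke-volume-driven pressure rise in the short task only |
| `sbp_noise_task_mult` | 2.2 (M) / 1.8 (F) | mechanical cost of producing each sigh raises beat-to-beat systolic scatter, equally at either pacing (drives HF-BPV) |
| `ptt_noise_task_mult` | 1 / 1.12 / 1.28 | vasomotor variability grows with load; the increment scales with `response_gain` |
| `rri_task_sd`, `bp_task_sd`, `ptt_task_sd`, `gain_task_sd` | 12 ms, 2 mmHg, 6 ms, 0.12 | between-task physiological state jitter, so subject-by-task residuals in the mixed models behave like real repeated measures rather than pure estimation noise |

The magnitudes of the per-sigh kernels, the task modulators, and the sex
scalings are free parameters — the source protocol documents the response
morphology and the direction of task and sex effects, not their amplitudes.
They were fixed once, to encode the qualitative direction pattern
(heart rate, LF-HRV, PTT variability, and LF-BPV graded across tasks with
males responding more; HF-HRV suppressed only under 15-s sighing, more so in
females; MAP elevated only under 15-s sighing; HF-BPV elevated equally in
both sighing tasks), and are not estimates of any cohort.

Sigh cues are laid on a grid starting half an interval into each segment
(`first_cue_frac = 0.5`). Centring the grid keeps sigh responses away from
segment boundaries — and therefore away from the tapered edges of the 60-s
Hann analysis windows, which are anchored at the segment start. With cues at
offset 0 every sigh lands within a second of a window edge, where the taper
weight is nearly zero, and the sighing-frequency comb is unmeasurable by
construction.

**What the generator does not emulate.** No PQRST morphology, no diastolic
waveform features, no baroreflex closed loop (the Mayer wave is imposed, not
emergent), no habituation or fatigue across sighs, no breathing-rate
variability, and no broadband 1/f HRV background — simulated log band powers
are therefore lower than typical cohort values even though band *ratios* and
task effects are realistic. Passing tests demonstrate that the pipeline
measures what the generator programmed; they do not certify performance on
noisy clinical recordings with ectopy, motion artifacts, or device drift
beyond the simple forms injected here.

## Beat processing conventions

* All channels are low-pass filtered at 10 Hz with a zero-phase
  (forward-backward) 4th-order Butterworth filter, so event times are not
  shifted.
* R peaks: local maxima above an adaptive threshold (half the robust spike
  height above the median) with a 250-ms refractory period.
* The systolic peak search window is `(R + 50 ms, next R)`: the guard skips
  any R-wave artifact in the pressure channel and guarantees the *subsequent*
  peak. PTT is `(BP-peak time - R time) * 1000` ms and is timestamped by the
  BP peak in the PTT series.
* Artifact correction replaces the manual editing step with an explicit rule:
  an RRI outside [300, 2000] ms, or deviating more than 30% from the 5-beat
  running median, is flagged and linearly interpolated; a record with more
  than 20% flagged beats is rejected. The rule is idempotent. An algorithmic
  stand-in was chosen because reproducibility requires one.
* Beats whose BP peak falls inside a pressure-calibration interval are
  excluded from every pressure-derived quantity (PTT variability, MAP, SBP
  spectra) while their RRI is retained.
* MAP is the per-beat time average of the pressure waveform over the beat's
  half-open window — the continuous signal reduced per beat by a stated
  convention, since "extracted directly" admits several readings.
* The RSA proxy is the delay (s) from a respiration peak to the next peak of
  the beat-indexed RRI series (the heart-rate trough); longer delays read as
  stronger cardiorespiratory synchronization. Every breath is eligible at
  baseline; only sighs are eligible during the sighing tasks. The RRI-series
  peak is located on the raw beat index (no interpolation); because an RRI
  value is stamped at the beat *ending* the interval, recovered delays sit up
  to about half a beat above the programmed coupling delay — within the
  one-beat quantization the proxy inherently carries.

## Spectral conventions

Beat series are cubic-spline resampled (natural splines) to 4 Hz over
`[first, last]` beat time, then passed through Welch's method: 60-s Hann
windows, 50% overlap, per-segment linear detrend, zero-padding to 2048
points, one-sided density normalized so that the integral approximates the
series variance (a 300-s task yields 9 segments). LF is 0.04-0.15 Hz, HF is
0.15-0.40 Hz, both integrated trapezoidally with exact interpolation at the
band edges and reported on the natural-log scale. Anything below 0.04 Hz is
excluded from band summaries — 5-minute records are too short for stable
very-low-frequency estimates — but the spectra retain the full grid, so the
sighing-frequency peaks at 1/30 and 1/15 Hz remain reportable:

```{r}
library(sighstress)
co <- simulate_process_cohort(24, seed = 1, keep_spectra = TRUE)
g <- average_spectra(Filter(Negate(is.null), co$spectra$long_interval$rri))
dominant_low_frequency(g)    # ~1/30 Hz
spectral_peaks(g)            # harmonics at ~2/30 and ~3/30 Hz
```

PTT variability (PTTv) is the within-task standard deviation of valid PTT
values, in ms — the definition is not pinned down by the source material, but
ms units make the SD the natural reading. BPV spectra are computed on
per-beat *systolic* values. Window choice (Hann) and detrend (linear) are
recorded in each spectrum's metadata.

## The mixed models

Each of the seven outcomes (HR, ln LF-HRV, ln HF-HRV, PTTv, MAP, ln LF-BPV,
ln HF-BPV) is fitted by REML as

```
outcome ~ task + sex + task:sex + covariates + (1 | subject)
```

with baseline as the reference task and a priori covariates: HR controls for
PWV and RSA; LF-HRV for RSA and HF-HRV; HF-HRV for RSA and LF-HRV; PTTv for
HR; MAP for PWV and HR (a `map_covariates = "hr_pttv"` switch offers the
HR + PTTv variant, since both appear in the source literature — neither is
asserted as the right one); LF-BPV for RSA and HF-BPV; HF-BPV for RSA and
LF-BPV. Covariates enter per task row (time-varying), the reading that makes
"controlling for respiratory-driven shifts" meaningful within person.

Design choices where the source is silent:

* **Random structure**: intercept per subject only. With three observations
  per subject, random slopes are not identifiable.
* **Degrees of freedom**: Satterthwaite, with type-III F tests — the standard
  repeated-measures convention in this field's software. Exact df matching to
  any published table is out of scope (they depend on undocumented
  exclusions).
* **Pairwise comparisons** (baseline vs long, baseline vs short, long vs
  short, averaged over sex) are reported regardless of omnibus significance
  and uncorrected for multiplicity; estimates satisfy the linearity identity
  `(short-BL) - (long-BL) = (short-long)` exactly.
* **Influence screening** is a single pass: Cook's D, the restricted
  likelihood distance (RLD), and externally studentized residuals are
  computed per observation by non-iterative case deletion — generalized
  least squares with the estimated marginal covariance held fixed, the
  convention behind the published screening thresholds (D > 1, RLD > 1.5,
  |studentized| > 4). RLD here is the displacement of the full-data
  restricted log likelihood when the fixed effects move to their
  case-deleted estimates, covariance parameters held fixed; also updating
  the residual scale would add O(1) chi-square noise per deletion and make
  any fixed cutoff meaningless. Flagged rows are removed and the model
  refitted once.
  Subjective criteria (improving a Q-Q plot by eye) are deliberately not
  implemented. The downdate algebra is exact: the test suite checks it
  against brute-force leave-one-out refits to 1e-8.

## Problem sizes and numerical choices

Default sampling is 250 Hz (configurable to 2000 Hz); all detection
tolerances are expressed in samples, so higher rates tighten them
proportionally. Spectral-signature checks use cohorts of 20-24 subjects;
model-recovery checks use table-level simulation at n = 250 with 200-replicate
null calibration at n = 50 — sizes at which every check completes on a
laptop-class single core in minutes. Degenerate inputs are handled
explicitly: flat channels yield empty peak lists with warnings; fewer than 4
valid beats refuse to spline; series shorter than one Welch window refuse to
transform; zero band power yields a missing log with a warning; a singular
mixed-model fit (zero between-subject variance) is kept at the boundary with
a warning; ties in the BP-peak search break to the earliest sample.

## Limitations

Simulated recordings are far cleaner than laboratory data: the artifact rule
is exercised by constructed corruptions, not by real ectopy; respiration is
strictly periodic between sighs; and the sex differences are programmed
directions, not biology. The acceptance checks therefore validate the
*pipeline* — detection accuracy, spectral calibration, model recovery,
influence algebra — and the protocol's frequency-domain signature, which is
determined by the sighing periods themselves, not by any cohort's
physiology.
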