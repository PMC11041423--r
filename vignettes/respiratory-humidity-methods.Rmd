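---
title: "Deriving respiratory parameters from humidity waveforms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving respiratory parameters from humidity waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhbreath)
```

## The measurement model

Exhaled air is saturated with water vapour, so a humidity sensor in the
airflow path of a face mask records one pulse per breath: the inhalation
trough sits near ambient relative humidity (RH) and the exhalation peak
approaches 100 %RH, with the peak height modulated by how much air was
moved. `rhbreath` treats the RH waveform as a proxy for ventilation: the
area under a breath pulse, above an ambient baseline, scales with the
volume of the breath. The package estimates

* respiratory rate (RR) by counting waveform minima per time window,
* tidal volume (TV) as the rectangle-rule area of a normal cycle between
  two consecutive minima,
* inspiratory and expiratory reserve volumes (IRV, ERV) as the areas of a
  deep breath's rising and falling limbs,
* vital capacity (VC) as IRV + ERV, and
* the deep-breathing area (DBA), the area of the closed deep breath, as
  the volume-agreement endpoint,

and compares them against a reference pneumotach (PNT) flow channel with
Bland-Altman, one-way ANOVA, RMSE, and correlation.

The core assumptions are (a) proportionality between pulse area and
breath volume within a recording — the constant is unknown a priori and
is estimated by linear calibration against the reference channel — and
(b) that breathing content lives well below 1 Hz, so the waveform can be
aggressively low-pass filtered without distorting breath morphology.

## Numerical estimators

**Rectangle rule.** Every area is a left-endpoint Riemann sum
`sum(max(f(x_i) - b, 0)) * dt` over a half-open sample interval. The
rectangle family is fixed by the method, the endpoint is a free choice;
left-endpoint is chosen and documented, and for band-limited breathing
signals the error is second order (the test suite verifies the error at
least halves when the sampling rate doubles). Values below the baseline
are clamped to zero so noise excursions below ambient cannot subtract
area.

**Integration baseline.** The ambient floor is taken as the recording's
5th percentile, a robust stand-in for ambient RH that ignores the
exhalation mass of the distribution. Whether to subtract a baseline at
all was a genuinely open design point; subtracting the ambient
floor makes areas meaningful across recordings made at different ambient
humidities. `rectangle_area()` accepts an explicit baseline for callers
who know better.

**Triangle comparator.** `triangle_area()` (shoelace area of the
start/peak/end vertices) exists only to show that the rectangle method
tracks reference volumes more closely; it is not used by the pipeline.

## Segmentation pipeline and its parameters

1. **Common grid, 100 Hz** (`grid_hz`). The humidity channel samples at
   up to 5 kHz and the reference at 1 kHz; both are decimated onto one
   grid before comparison. For integer decimation factors ≥ 4 the
   resampler uses a centred block average per output sample (zero phase,
   exact DC gain, first spectral null at the output rate), otherwise a
   zero-phase Butterworth low-pass at 0.45 of the target rate followed by
   linear interpolation. 100 Hz leaves two decades of headroom above
   breathing content.
2. **Smoothing, 2 Hz cutoff** (`smooth_cutoff_hz`). A forward–backward
   (zero-phase) Butterworth filter of order 4. The mean is subtracted
   before filtering and restored afterwards, and the signal is
   odd-reflected at both ends, so constants pass through exactly and edge
   transients are suppressed. Smoothing is essential before double
   differentiation: at the sensor's 0.02 %RH noise level an unsmoothed
   second difference is useless.
3. **Extrema** (`min_prominence`, default 1 %RH; `min_separation_s`,
   default 1 s). Minima and maxima must clear a topographic prominence
   threshold and a mutual separation; 1 s caps the detectable rate at 60
   breaths/min. Plateau ties resolve to the first sample of the plateau,
   and runs of same-type extrema are collapsed to the most extreme
   member so minima and maxima alternate. The prominence search is
   bounded to a 30-s neighbourhood per peak; breathing valleys return to
   baseline within one breath, so this changes nothing while keeping the
   cost linear on saturation-plateau signals. The pipeline adapts the
   prominence to each channel (20% of the 1st–99th percentile range) so
   the same code segments %RH and L/s waveforms.
4. **Cycles.** Consecutive minima delimit cycles (half-open index
   intervals, 1-based as is natural in R); the enclosed maximum is the
   peak; amplitude is peak minus the lower trough.
5. **Deep breaths** (`duration_k = 1.21`, `area_k = 0.8`). A deep
   inhale–exhale is both larger and longer than a tidal breath, but
   saturation near 100 %RH compresses amplitudes — a saturated tidal
   breath and a weak deep breath can share the same peak, and a deep
   breath can even have *less* amplitude than a large tidal breath.
   Duration is therefore the discriminator: tidal cycle durations jitter
   by a few percent around the subject's period while a deep breath takes
   about 1.5 periods, leaving a clean gap around 1.21× the median cycle
   duration. The area floor (0.8× median area) only prevents long
   near-flat pauses from being read as deep breaths. Medians are taken
   over the whole recording by default; a rolling window is available for
   recordings whose rate drifts, at the price of noisier references near
   the edges.
6. **Limb refinement.** Within a flagged cycle, the deep-inspiration
   onset and deep-expiration end are moved to the nearest sign change of
   the smoothed signal's second derivative inside the rising and falling
   limb respectively (ties resolve to the earlier sample). The refined
   limbs delimit IRV and ERV; the DBA uses the full trough-to-trough
   span. Keeping DBA on the full span matters for device comparison: the
   inflection-bounded sub-area captures a different fraction of a
   humidity pulse than of a flow pulse, so an inflection-bounded DBA
   would inject a systematic device difference that is an artifact of
   waveform shape, not of measurement quality.
7. **Respiratory rate** (`window_s = 60`). Counted from minima in
   non-overlapping left-aligned windows, count × 60 / window. The
   literature describes counting both maxima and minima; minima are the
   default for consistency with cycle boundaries, and passing the maxima
   vector gives the other convention (the suite checks the two agree
   within 1 breath/min).

## Calibration and agreement statistics

Reference volumes are the per-cycle integrals of the PNT flow channel —
the pipeline treats the reference device as ground truth, which is its
role in a validation study. Per subject, a least-squares line maps RH
cycle areas (%RH·s) to matched reference volumes (L); areas are reported
uncalibrated by default so that uncalibrated numbers are never dressed up
as liters.

`bland_altman()` uses the classical estimator: bias = mean difference,
LoA = bias ± 1.96 × sample SD. Published LoAs for this kind of data are
asymmetric, implying an unstated transformation, so two refinements are
provided without being defaulted: a log-scale mode (asymmetric
back-transformed limits) and a mixed-effects mode with per-subject random
intercepts in which the between-subject variance component is kept only
when it improves AIC by more than 2 points — this package's concrete
reading of the variance-component zeroing rules that population
Bland-Altman analyses usually describe only loosely.
Per-subject mean normalization is available for heteroscedastic volume
data.

`one_way_anova()` delegates the decomposition to `stats::aov()` and
re-derives the table; degenerate cases are made explicit (all values
identical → F = 0, P = 1; zero within-group variance with distinct means
→ P = 0 with a degeneracy flag). `anova_from_summary()` rebuilds MS, F,
and P from a printed SS/df decomposition, making published tables
checkable without the raw data; the suite confirms it is self-consistent
with the full ANOVA to 1e-12. Note that published summary tables are not
always internally consistent — the respiratory-volume row of the table
this package re-derives prints a mean square that does not equal SS/df;
`rhbreath` always reports the self-consistent values. Quartiles use
linear interpolation (type 7), the R default, since no convention was
stated.

The pipeline pools windows and deep events across subjects as independent
observations in the device ANOVA. That mirrors the published analysis
(346 within-group degrees of freedom for ~15 windows × 7 subjects × 2
devices is only explicable by per-window pooling) but is
pseudo-replication in the strict sense; the mixed-effects LoA mode is the
package's acknowledgement of the issue.

## The synthetic cohort: what it does and does not emulate

`simulate_subject()` renders each breath as a raised-cosine pulse
(half-cosine inhale, half-cosine exhale) — smooth and twice
differentiable, which the second-derivative detector requires — from the
ambient baseline (default 40 %RH) to a per-cycle exhalation peak drawn
from the envelope distribution (mean 89, SD 7.8 %RH), clipped at
saturation (100 %RH) after noise is added. Cycle periods are truncated
normal (±3 SD) around 60/17.6 s with an SD equivalent to 1 breath/min —
a realistic quiet-breathing variability. Every 30 s (first event half a
period in, giving 30 events per 15-minute recording) a deep breath scales
the excursion by 2 and the duration by 1.5; real deep breaths both
saturate the sensor and take visibly longer, and amplitude scaling alone
is invisible under the saturation cap. Sensor imperfections are additive
Gaussian noise (0.02 %RH, the sensor datasheet figure) and linear drift
(0.05 %RH/min by default). After the last complete cycle the generator
renders the beginning of one more breath, as a real recording cut
mid-breath would show — a flat tail would make the final cycle boundary
an undetectable zero-prominence minimum.

Ground truth links areas to volumes through a fixed gain (0.006 L per
%RH·s), chosen so a normal breath is ~0.5 L — the proportionality is
asserted by the physics, the constant is the package's choice. The
reference flow channel carries one half-sine pulse per cycle whose
integral equals the cycle's true volume exactly (quadrature aside), plus
its own independent noise (0.005 L/s), so the two channels share breath
timing and volume but not noise. `simulate_population()` draws
per-subject parameters (rate SD 1.7 breaths/min, envelope SD 3 %RH, 10%
relative gain spread) and derives one RNG stream per subject from the
study seed, so cohorts are reproducible element-wise.

What the generator does **not** emulate: movement artifacts, temperature
and pressure coupling, sensor response-time asymmetry between inhale and
exhale, apnoea, and genuinely pathological breathing. Anomalies are
limited to the two artifact classes seen in mask recordings — saccades
(superimposed mid-cycle oscillation) and missing ventilatory recovery (a
trough that fails to return to baseline) — injected on demand with the
anomaly window recorded in the truth. Passing tests on this cohort
therefore show that the algorithms recover the parameters of *clean
protocol-compliant breathing* at datasheet noise; they do not certify
performance on clinical recordings.

Two structural consequences of the design are worth knowing. Because
deep breaths take 1.5 tidal periods, windows containing deep breaths
count fewer breaths: the counted RR sits below the quiet-breathing rate
parameter, and RR recovery against that parameter is only exact when the
deep-duration factor is 1 (the suite tests it that way; against windowed
ground-truth counts recovery holds regardless). And because both
channels derive from the same truth, between-channel RR differences are
essentially zero — far tighter than any real device pair — so the
simulated limits of agreement are much narrower than published ones; the
pipeline's value is demonstrating the *null* (no device effect), not
reproducing field-width LoAs.

## Problem sizes and runtime choices

The test suite exercises short recordings (120–180 s at 500 Hz RH / 250
Hz flow) for unit behaviour, the full default study (7 subjects × 900 s
at 5 kHz / 1 kHz) for parameter recovery and the end-to-end null, and
100 replicates of a reduced two-subject, 150-s study for the
false-positive-rate calibration of the device ANOVA (nominal 5%,
accepted ≤ 10%). These sizes keep a complete run in the low minutes on a
single CPU while leaving every scientific claim tested at the scale it
is made.

## Telemetry and file formats

Raw sensor frames arrive as 8-hex-character IEEE-754 single-precision
floats; `decode_ieee754_hex()` defaults to big-endian (network order)
with a flag for little-endian, since the transmitting firmware's byte
order is not documented. Non-finite payloads decode faithfully and are
flagged rather than dropped. Time series are exchanged as `time_s,value`
CSV with a `# units:` sidecar comment; the reader infers the rate from
the median timestamp spacing and rejects files whose spacing jitters by
more than 0.5%, naming the first offending row. All CSV I/O uses comma
separators, `.` decimals, and UTF-8, so write→read round trips are
deterministic.

## Known limitations

* The duration-based deep-breath detector assumes tidal period jitter
  well below the deep-breath duration factor; erratic breathers (jitter
  approaching ±25%) would need the rolling-median mode and looser
  thresholds, at the cost of detection errors.
* Calibration regresses the device on the reference per subject, which
  partially absorbs device scale error into the agreement statistics —
  unavoidable when the area-to-volume constant is unknown, and shared
  with the study design the package mirrors.
* Residual volume is not measurable from this signal, and no absolute
  spirometric standard is implemented.
* The simulator honours the reported 5 kHz humidity sampling rate even
  though it exceeds what commodity humidity sensors natively achieve;
  the discrepancy is noted here rather than resolved.
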