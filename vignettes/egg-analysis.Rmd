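---
title: "Gastric slow-wave analysis with eggwave: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gastric slow-wave analysis with eggwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggwave)
```

## The measurement problem

Cutaneous electrogastrography (EGG) records the stomach's myoelectrical
slow wave from abdominal surface electrodes. The signal is unusually
hostile to measurement: its amplitude is 200–500 µV peak-to-peak, an
order of magnitude below ECG, and its spectrum sits almost at DC — the
healthy (normogastric) rhythm occupies 2–4 cycles per minute (cpm),
i.e. 0.033–0.067 Hz, with the physiologically meaningful band extending
from roughly 0.016 to 0.15 Hz. Shifts of the dominant rhythm into the
tachygastric band (4–10 cpm) accompany nausea, which makes EGG a
candidate objective marker of simulator sickness in driving and VR
simulators. Recording *during* simulated driving, however, exposes the
electrodes to motion artifacts that can dwarf the signal.

`eggwave` implements the complete sensing-and-analysis chain for such
studies: a digital twin of a three-channel analog front end, a seeded
synthetic-EGG generator with ground truth, band-pass preprocessing,
channel selection and artifact excision, five per-segment slow-wave
features, Simulator Sickness Questionnaire (SSQ) scoring, and the
session/cohort workflow with paired comparisons.

## The front-end twin

Each acquisition channel is modelled as an instrumentation amplifier
followed by two unity-gain, equal-component Sallen–Key stages:

$$H(s) = G \cdot \frac{s^2}{(s+\omega_{hp})^2}
           \cdot \frac{\omega_{lp}^2}{(s+\omega_{lp})^2},$$

with $G = 1 + R_{const}/R_g$ (the INA114 gain law; 1001 at
$R_g = 50\,\Omega$, nominally quoted as 1000) and $\omega = 1/(RC)$:
each stage contributes a *double real pole* at $f = 1/(2\pi RC)$. With equal resistors and capacitors and
unity gain, the Sallen–Key quality factor is $Q = 1/(3-K) = 1/2$, which
is exactly the coincident-pole case; this is why the magnitude at the
pole frequency sits 6.02 dB (not 3 dB) below the plateau. The default
components give a high-pass pole at 0.0159 Hz (0.016 Hz rounded) and a
low-pass pole at 4.823 Hz.

`acquire()` discretises the two stages by the bilinear transform at a
dense internal rate (250 Hz by default; pole frequencies are four
orders of magnitude below the internal Nyquist, so frequency warping is
negligible) and then subsamples to the 2 Hz output rate **without any
additional digital anti-aliasing**. That is deliberate: the hardware's
analog low-pass at ≈4.8 Hz cannot prevent aliasing at a 2 Hz sampling
rate, and the twin reproduces this property — a 1.2 Hz ECG-like
component aliases to 0.8 Hz, exactly as in the device. A 16-bit
quantiser over ±5 V can be enabled to emulate the ADC; it is off by
default because its effect is far below the physiological noise floor.

A consequence worth stating explicitly: the second-order high-pass at
0.016 Hz still attenuates the 3 cpm (0.05 Hz) slow wave by about 9 %
($|H| \approx 0.91 G$), so amplitude-calibration tests in this package
always compare against the closed-form $|H(j2\pi f)|$, not against
$G$ alone.

Recordings store the EGG channels *input-referred* (the acquired signal
divided by $G$, with $G$ kept in the JSON sidecar). This keeps stored
samples and therefore reported RMS in the physiological 0–0.4 mV range
in which such studies plot their results.

## The synthetic-EGG generator

No public EGG recordings accompany this workflow, so the generator is
the test bed for every downstream stage. It is phenomenological — it
reproduces the statistical structure the analysis assumes, not gastric
electrophysiology:

* **Slow wave.** A sinusoid with piecewise-constant frequency
  (baseline 3 cpm; dysrhythmic episodes override it, e.g. 6–8 cpm
  tachygastria) integrated to a continuous phase, amplitude 300 µV
  peak-to-peak by default (mid-range of the physiological 200–500 µV).
  Episode amplitude changes are ramped with 5 s cosine flanks so that
  amplitude steps do not inject broadband energy that would confound
  spectral tests.
* **Propagation lag.** Channels are gain-scaled, time-lagged copies of
  the same gastric source (defaults 0, 0.5, 1 s), because the slow wave
  reaches the three electrode sites with a physiological delay —
  whereas motion artifacts do not.
* **Contaminants**, independent per channel: respiration (0.3 Hz
  sinusoid, 20 µV), an ECG-like Gaussian pulse train (1.2 Hz, 50 µV,
  40 ms FWHM — only its alias power at the 2 Hz output rate matters, so
  no PQRST morphology is modelled), and baseline drift (Gaussian noise
  through a one-pole low-pass at 0.005 Hz, 50 µV SD, emulating
  electrode-offset wander).
* **Motion-artifact spikes.** Gaussian pulses of width 1 s injected at
  identical times on all three channels (`simultaneous = TRUE`), at 5×
  the slow-wave peak by default — a repository convention; published
  figures show "large" spikes without quantifying them.

All randomness is drawn under one integer seed in a fixed order, so a
configuration reproduces to the last bit. Ground truth (per-interval
dominant frequency, RMS scaling, spike markers) is returned alongside
the signals and drives the parameter-recovery tests.

What the generator does **not** emulate: non-sinusoidal slow-wave
morphology, amplitude modulation by the respiratory cycle,
electrode-detachment transients, 50 Hz hum (irrelevant after the analog
chain), and inter-subject spectral variability beyond frequency and
amplitude. Passing recovery tests therefore show that the pipeline
measures what it claims on signals with the assumed structure — not
that it is robust to every failure mode of real electrodes.

## Preprocessing

The digital stage is a 3rd-order Butterworth band-pass, 0.03–0.25 Hz
(1.8–15 cpm). It is applied **zero-phase** (forward and backward) by
default: segment boundaries come from a synchronisation channel, so
preserving alignment and slow-wave morphology is worth the doubled
effective magnitude order, and a single-pass mode
(`bandpass_spec(zero_phase = FALSE)`) exists for literal replication of
a causal analysis. Numerically, the cutoffs sit far below the 1 Hz
Nyquist; the direct transfer-function form of the filter was checked to
be well conditioned here (pole moduli ≤ 0.961), so the package uses the
standard `signal::butter` coefficients. Edge transients of a 0.03 Hz
filter are long relative to 5-min segments, so the input is padded by
odd reflection over three periods of the low cutoff (100 s at 2 Hz)
before filtering and trimmed afterwards.

Filtering is applied to the whole recording before segmentation (the
alternative — per segment — is available by slicing first); whole-record
filtering avoids spending the transient inside analysed segments.

## Channel selection and artifact excision

The robustness procedure has two steps. First, *automatic selection*:
on the band-passed channels, any channel whose amplitude range
(max − min) is at least 100 % higher than the others is eliminated, and
the lowest mean-of-squares power channel among the survivors is chosen.
"The others" is operationalised as the *minimum* of the other channels'
ranges — the strictest reading, which can never eliminate the cleanest
channel and therefore always leaves a survivor; `others = "mean"` and
`"max"` are provided as configurable alternatives since the verbal rule
is ambiguous. Ties in power break to the lowest channel index.

Second, *manual excision*: artifacts are marked as closed-open
`[start_s, end_s)` intervals and `excise()` deletes the samples inside
them, concatenating the remainder as a gapless series. Spectral
smearing at the junctions is accepted — the analysis this package
follows did the same — and the total excised duration is reported so
that segments that become too short are flagged rather than silently
producing degraded features.

`detect_simultaneous_spikes()` is a convenience pre-screen, never an
auto-applier: it flags 2 s windows in which **all three** channels
exceed 5 robust z-scores. The z-score is computed on the first
difference of each channel: differencing shrinks the slow wave (whose
sample-to-sample change at 3 cpm is a few tens of µV) while a spike
keeps its full excursion, so the screen works equally on raw and
band-passed data. Median/MAD statistics keep the threshold meaningful
when spikes are present. Final artifact marking remains a human
decision, in line with practice in this field.

## The five slow-wave features

All spectral features are computed on the mean-removed segment, FFT
zero-padded 4× for bin interpolation, restricted to the analysis band =
the band-pass passband (0.03–0.25 Hz; outside it the spectrum reflects
the filter, not physiology).

* **DF (dominant frequency, cpm)** — the maximum-magnitude bin,
  refined by parabolic interpolation of the three bins around the peak;
  ties go to the lowest frequency.
* **MF (median frequency, cpm)** — the frequency dividing the power
  spectrum into equal halves, interpolating the cumulative power
  linearly between bins. When the cumulative curve is flat at exactly
  half (two equal-power peaks), the midpoint of the flat region is
  returned. MF is the feature that actually tracks tachygastric shifts:
  DF stays at the global peak while MF moves with the mass of the
  spectrum.
* **CF (crest factor, dimensionless)** — peak magnitude divided by the
  RMS *of the magnitude spectrum* over the analysis band. Whether the
  published definition's "its RMS" refers to the spectrum or to the
  time-domain signal is genuinely ambiguous; the spectrum reading is
  the default (a flat spectrum then gives exactly 1, a one-hot spectrum
  $\sqrt{n}$), and `denominator = "signal"` implements the other
  reading.
* **RMS (mV)** — time-domain root mean square; stored µV are divided
  by exactly 1000 at this reporting boundary.
* **Normogastric power fraction (%)** — Welch PSD integral over
  2–4 cpm divided by the integral over the analysis band. The
  denominator is the analysis band, not the full Nyquist band, so the
  fraction is comparable across identically filtered segments; with
  that choice the normogastric and non-normogastric in-band fractions
  sum to 100 exactly. Welch defaults: 120 s Hann windows at 50 %
  overlap — at least two windows in a 5-min segment while still
  resolving 0.5 cpm; the published analysis states no Welch
  parameters, so these are the package's own.

Rhythm classification uses closed normogastric boundaries: 2–4 cpm
inclusive is normogastric (a 4 cpm tie is normogastric, not
tachygastric), below 2 bradygastric, 4–10 tachygastric, above 10 out of
band.

## SSQ scoring

The 16 symptoms are rated 0–3 (none / slight / moderate / severe). The
standard instrument assigns each symptom to one or two of three
subscales — nausea, oculomotor, disorientation — each subscale summing
exactly seven ratings, and scores are the raw sums times 9.54, 7.58 and
13.92 respectively, with the total = (sum of the three raw sums) ×
3.74. The study this package serves prints only the four uniform-rating
anchors (total 0 / 78.54 / 157.08 / 235.62, nausea 0 / 66.78 / 133.56 /
200.34); those anchors fully constrain and verify the shipped item
table and weights, and they are what the acceptance checks recompute.

## Session and cohort workflow

A session records ~30 min: a familiarisation test drive, a resting
baseline and two ~5-min drives (with and without platform motion,
order counterbalanced), with SSQ forms between segments. A force
sensing resistor (FSR) pressed at the start and end of each analysed
segment synchronises the EGG record with the protocol: six presses
delimit three segments. Press events are upward crossings of half the
FSR maximum, debounced at 2 s; any other event count is a
synchronisation error that reports the detected press times. The
output table always lists resting before the drives, whatever the
recorded order, so the counterbalancing never leaks into downstream
comparisons.

`extract_segment_features()` runs band-pass → channel selection →
excision → features per segment and records the chosen channel, the
eliminated channels and the excised duration. `run_study()` adds
per-subject error isolation (a failing subject is excluded *and
reported*, mirroring the 4-of-13 exclusions typical of such cohorts),
per-feature paired t-tests between each condition pair, SSQ scoring and
the demographic summary, and writes the report bundle as plain CSVs.
When artifact markers exist the features are computed with and without
excision so corrected/uncorrected pairs can be plotted
(`plot_rms_normo()` draws the arrows).

`paired_t_test()` wraps `stats::t.test(paired = TRUE)` — $t =
\bar d/(s_d/\sqrt n)$ on $n-1$ degrees of freedom — and the test suite
verifies it against the direct formula with the two-sided p-value
obtained by numerically integrating the t density, to $10^{-6}$ over
100 random instances. No multiple-comparison correction is applied,
matching the workflow this package reproduces.

## Why simulation-based validation

The cohort statistics published for this workflow (e.g. a paired
p = 0.03 between resting and no-motion RMS in nine subjects) were
computed on recordings that were never deposited, so they cannot be
recomputed. The package's validation therefore rests on properties the
generator can enforce: DF recovers the generated frequency within
0.3 cpm in ≥ 90 % of 50 seeded segments spanning 2.5–8 cpm; MF rises
monotonically with the fraction of a segment spent tachygastric;
doubling the generated amplitude doubles measured RMS within 3 %
(contaminants held fixed); channel selection avoids a spike-corrupted
channel in ≥ 99 of 100 seeded trials; excising a marked spike strictly
lowers RMS; and a simulated nine-subject cohort whose drives carry a
50 % RMS amplification (10 % inter-subject log-normal variability)
yields a paired p < 0.05 in the clear majority of 200 replicates.

## Numerical and scale choices

Problem sizes in the test suite are the package's own: 100 Hz internal
generation (validity requires ≥ 50× the 2 Hz output; 250 Hz remains
the user-facing default), 180–300 s segments for pipeline tests, 600 s
for steady-state amplitude calibration. Degenerate inputs fail loudly
with typed messages: zero-MAD channels in the spike screen, zero band
power in MF and the power fraction, all-identical paired differences
in the t-test, out-of-range markers in excision, empty segments
everywhere. Intervals are closed-open so that excision and
concatenation compose without double-counting boundary samples;
same-label markers are merged to their union on construction, making
normalisation idempotent.

## Known limitations

* The generator's sinusoidal slow wave makes spectral features easier
  to estimate than on real EGG; recovery rates here are upper bounds.
* The front-end twin models ideal components: no tolerances, op-amp
  non-idealities, electrode impedance or leakage currents.
* Channel selection assumes exactly three channels, as the hardware
  provides.
* The crest-factor definition retains a genuine ambiguity (spectrum vs
  signal RMS); results using the non-default reading are not directly
  comparable.
* Automatic spike proposal is a screen, not a substitute for expert
  marking; single-channel artifacts are deliberately out of its scope.
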