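---
title: "Automated characterization of patient-ventilator interaction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated characterization of patient-ventilator interaction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsync)
```

## The problem

Mechanically ventilated, critically ill patients frequently breathe against
or out of phase with the machine. A temporal mismatch between a patient's
inspiratory effort and the ventilator's pressure support - an *asynchrony* -
is associated with longer ventilation, weaning failure and discomfort.
Quantifying it requires knowing when the patient tried to breathe, which is
normally read from invasive signals (esophageal pressure Pes, or diaphragm
EMG from an esophageal catheter) by trained staff.

`ventsync` implements a fully automated, noninvasive alternative: patient
inspiratory efforts are detected in *surface* EMG (sEMG) of the diaphragm
and parasternal/intercostal muscles, ventilator insufflations are segmented
from the airway pressure (Paw) waveform, each breath is assigned one of six
interaction classes, and an asynchrony index (AI) summarizes the recording.
A synthetic ventilated-patient generator with scripted ground truth makes
every stage testable without clinical data.

## Signal model and preprocessing

Channels are uniformly sampled time series: pressures and flow at 100 Hz,
sEMG at 1000 Hz. The sEMG chain is:

1. **Powerline removal** - zero-phase IIR notches (0.8 Hz bandwidth) at the
   mains frequency and harmonics. The narrow bandwidth keeps the passband
   within 0.5 dB outside +/- 2 Hz of each notch.
2. **Cardiac artifact removal** - QRS complexes are detected on a 5-30 Hz
   band-passed copy (amplitude threshold, 250 ms refractory); beats are
   aligned by cross-correlation, a median template (+/- 100 ms) is built,
   and each beat is removed by least squares over the template and its
   derivative (the derivative term cancels residual sub-sample
   misalignment, which otherwise dominates the residue). Estimation runs on
   an idempotent spectrally mains-masked copy, so the result does not
   depend on whether powerline filtering ran first. Windows are detrended
   by a line fitted on their outer 20 % - where the cardiac pulse has
   decayed - so slow baseline content is never subtracted. With fewer than
   3 beats the signal passes through with a warning.
3. **RMS envelope** - causal root-mean-square over a 250 ms window
   (reflection-padded), advanced by `lag_shift_ms` and decimated to 100 Hz
   to align with the pressure channels. The default advance is half the
   window (125 ms): it removes the moving-RMS group delay exactly for this
   window; the cohort-specific neuromechanical lag that a clinical
   deployment would calibrate is not knowable here, so the geometric value
   is the default and the parameter is exposed.
4. **Channel validity** - a channel enters segmentation only if the
   envelope SNR inside vs outside its own detections reaches 6 dB
   (inclusive) and at least 5 activities were found. Both limits are
   declared defaults (config-overridable); with no valid channel the
   pipeline returns supports-only output and an undefined AI.

The same template machinery suppresses the cardiogenic ripple in Pes
(window +/- 150 ms at 100 Hz). Respiratory-band content below 2 Hz is
preserved because only the beat-locked template - never the window
baseline - is subtracted.

## Effort detection

Two detectors run on the envelope, reflecting two operating points:

**Triangle algorithm** (robust, precise onsets). Per 30 s analysis window
with baseline `b` (5th percentile) and maximum `M`, candidate peaks are
local maxima above `b + 0.4 (M - b)`; the 40 % relative threshold is the
method's defining constant. For each peak the onset is the *elbow* of the
rising edge: the point between the preceding minimum and the peak with
maximal perpendicular distance to the chord joining them, computed on
axis-normalized coordinates so all event times are invariant to envelope
scaling. A peak only counts as a new burst if the envelope fell below the
offset fraction of its height since the previous peak (otherwise it is a
ripple on ongoing activity). Events closer than 300 ms are merged. Trailing
window fragments shorter than half a window are folded into the previous
window so that a leftover strip of pure noise is never scaled into
detections.

**Adaptive thresholding algorithm** (sensitive). Running noise statistics
`mu, sigma` with exponential forgetting (2 s time constant) are updated
only while the envelope is at or below the threshold
`T = max(mu + 3 sigma, mu + threshold_floor)` and frozen during activity.
An effort starts at the first sample of a run above `T` sustained >= 60 ms.
After the event ends the detector re-arms only once the envelope returns
below `T`; without this hysteresis a single burst's falling edge would
splinter into a staircase of events. `threshold_floor` defaults to 0.5 uV:
below the smallest physiological burst of interest but above the residual
cardiac bumps that template subtraction leaves on a ~1 uV noise floor.

Both detectors end an event by the classic offset rule: the effort ends at
the first time after the envelope peak where the baseline-referenced
envelope drops below 70 % of its peak. The same 70 % rule, applied to the
muscular pressure Pmus, finalizes reference segmentations.

When both sEMG channels are valid, overlapping events are fused taking the
*earlier* onset as the start of electrical activity. Fused offsets use the
latest offset (the union of the evidence); whether the earliest or latest
offset is the better convention is unresolved, and the choice does not
affect trigger-delay computations, which use onsets only.

## Pes, volume and Pmus

Flow is integrated trapezoidally to volume with a piecewise-linear drift
correction pinned to zero at each detected end-expiration. Chest-wall
elastance Ecw is the least-squares slope of Pes against volume over
*passive* (effort-free) intervals - passivity cannot be inferred from Pes
alone, so the intervals are an explicit input (the generator exports them).
The muscular pressure is

    Pmus(t) = Ecw * V(t) - (Pes(t) - Pes_baseline),

positive during inspiratory effort, ~0 during passive breaths. The sign
convention makes the 70 % offset rule read identically for Pmus and the
sEMG envelope.

## Support segmentation and classification

A mechanical breath starts at the first sample of the positive Paw ramp and
ends at the first sample of the falling edge. Operationally, PEEP is the
density mode of the lower part of the smoothed waveform; a pressurization
is flagged 1 cmH2O above PEEP, and the ramp foot is found by extrapolating
the initial ramp slope back to the PEEP level - exact on clean ramps and
robust to noise, where sample-by-sample backtracking is biased by
autocorrelated noise. Cycling-off is the first sustained (30 ms) drop of
the smoothed derivative below -20 cmH2O/s. Hysteresis, slope threshold and
the 200 ms minimum duration are declared defaults of this implementation.

Efforts and supports are paired by positive-duration interval overlap
(touching endpoints do not overlap). For each overlapping pair the trigger
delay is `dt = t_Paw - t_patient`. The six classes:

* one effort, one support, `dt <= 250 ms` -> **synchronous** (inclusive
  boundary; a negative delay also satisfies the one-sided rule - reverse
  triggers are explicitly out of scope, so no separate class exists);
* same with `dt > 250 ms` -> **delayed**;
* effort with no support -> **ineffective**; support with no effort ->
  **auto-trigger**;
* one effort over k >= 2 supports -> first support by its delay, the rest
  **double triggers**; k >= 2 efforts under one support -> the later ones
  **double efforts**.

Components of the overlap graph with several efforts *and* several supports
generalize the two published constellations: the earliest effort pairs with
the earliest support (labeled by delay), surplus supports are double
triggers, surplus efforts double efforts. This reduces exactly to the
stated rules in every constellation they cover.

The asynchrony index is the number of major asynchronous events
(ineffective, auto- and double triggers, double efforts) divided by the
total number of breaths. "Total breaths" is not operationally defined in
the source literature; this package counts ventilator insufflations plus
ineffective efforts (the Mojoli/Thille convention), with
`supports_plus_unsupported` available as an alternative denominator.

## Validation machinery

* **Expert consensus** - two annotators' onsets are paired greedily by
  nearest time; pairs within 250 ms are averaged, everything else is
  invalid. Greedy one-to-one pairing is a declared choice: the published
  rule states the tolerance but not the multiplicity handling.
* **Detection metrics** - a detection overlapping a reference effort is a
  true positive (greedy one-to-one by onset proximity; surplus detections
  are false positives), non-overlapping detections are false positives,
  unmatched references false negatives; onset bias/SD over matched pairs.
* **Confusion table** - 7x7 (six classes + "not detected"), reference on
  rows, aligned via shared supports, then effort overlap.
* **Repeated-measures Bland-Altman** - differences are decomposed by a
  one-way random-effects model (subject as random factor, unequal group
  sizes via the standard n0 correction); `sd_total^2` is the
  between-subject plus within-subject variance and the limits are
  `bias +/- 1.96 sd_total`. With one pair per subject this reduces to the
  classic method; negative between-subject variance estimates are clamped
  to zero.

## The synthetic world

The generator scripts one event constellation per breath cycle and renders
coupled waveforms from it; the scripted table *is* the ground truth, so
class counts match the requested mix exactly (largest-remainder rounding).
Stated conditions: respiratory rate 15/min; pressure support 8 cmH2O above
PEEP 5 with a 150 ms rise; single-compartment mechanics R = 10
cmH2O/(L/s), E = 25 cmH2O/L (so expiration decays with tau = 0.4 s and
volume returns to < 1 % of tidal at end-expiration); chest-wall elastance
5 cmH2O/L; Pes effort deflection 8 cmH2O with a ~1 cmH2O cardiogenic
ripple and baseline 3 cmH2O; sEMG bursts are raised-cosine
amplitude-modulated 20-250 Hz noise at 16 uV peak on a 1 uV noise floor
(about 20 dB in-burst power ratio), contaminated by a repeated biphasic
~80 ms QRS template at 80 bpm (60 uV, +/- 5 ms jitter, +/- 10 % amplitude
variation) and a 20 uV 50 Hz mains line. Synchronous trigger delays are
drawn from [0.05, 0.25] s and delayed triggers from (0.25, 0.6] s,
straddling the 250 ms class boundary. Double triggers are one long effort
spanning two supports; double efforts two efforts under one support.
These values are the published settings where printed and field-typical
ICU pressure-support numbers otherwise; they are fixed once and not tuned.

What the generator does **not** emulate: muscle crosstalk, motion
artifacts, electrode failures, drifting electrode impedance, reverse
triggers, nonlinear respiratory mechanics, or the heavy-tailed noise of
real ICU recordings. A green test therefore establishes algorithmic
correctness under the stated statistical structure - not clinical
performance, which the source study measured on 84 ICU recordings that are
not publicly deposited.

## Numerical choices and degenerate inputs

* Intervals are closed, all times in seconds from recording start; one
  convention across the 100/1000 Hz channels.
* Resampling is Fourier-domain (spectrum truncation/zero-padding): exact
  for band-limited input, DC preserved exactly; edge ringing is negligible
  for the smooth envelopes it decimates.
* Tie-breaks: equal chord distances in the triangle elbow -> earliest time
  wins (`which.max` semantics); equal-distance consensus pairs -> first in
  scan order.
* Flat envelopes (excursion below `threshold_floor`) yield no events; a
  monotone envelope returns the search bound as offset; a non-positive
  Pmus segment flags the effort as degenerate.
* `estimate_ecw` refuses constant-volume regressions; `classify` rejects
  overlapping intervals within one event list; AI with zero breaths is
  returned as undefined with a flag rather than NaN.
* Storage is a delimited-text container (one CSV per channel + JSON
  sidecar): the source format is unspecified, any lossless container is
  acceptable, and no EDF reader is available in the dependency stack.

## Known limitations

* The exact filter designs, detector pseudocode and the cohort-optimized
  envelope lag of the source method live in its supplement; this package
  honors every main-text statement and declares its own defaults for the
  rest, all config-exposed.
* The end-of-recording second of signal can carry an edge artifact from
  zero-phase filtering (a partially corrected final heart beat); the
  sensitive detector may emit one false positive there.
* Auto-triggers cannot be distinguished from ventilator fallback controlled
  breaths without a machine trigger signal; cycling-off (expiratory)
  asynchronies and reverse triggers are out of scope.
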