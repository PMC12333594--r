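---
title: "Interhemispheric phase asymmetry: models, statistics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric phase asymmetry: models, statistics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiphase)
```

## The scientific question

When an observer watches another person's face and judges whether that
person is lying, does the judgment leave a signature in the observer's EEG?
Event-related potential (ERP) amplitudes often do not discriminate such
subtle social evaluations. This package implements a complementary set of
analyses that look instead at *interhemispheric asymmetry*: systematic
left–right differences in signal magnitude, in instantaneous phase
progression, and in spectral content, between homologous electrode pairs of
a 10–20 montage (F3–F4 … O1–O2, twelve pairs in all, always signed left
minus right).

The centerpiece is the **conditioning interhemispheric phase shift**. For
one electrode pair and one trial, the interhemispheric phase shift is the
difference of the two electrodes' unwrapped instantaneous phases,

$$\Delta\phi(t) = \phi_L(t) - \phi_R(t),$$

where $\phi(t)$ is the angle of the analytic signal $g(t) + i\,\hat g(t)$
and $\hat g$ is the Hilbert transform, computed in the discrete Fourier
domain by zeroing negative frequencies. Because instantaneous phase is the
integral of instantaneous frequency, the slope of $\Delta\phi$ against time
measures the average frequency difference between the two hemispheres: a
slope of $2\pi f$ rad/s means the left electrode runs $f$ Hz faster.

The conditioning statistic for one subject is the absolute difference of
the two condition means of $\Delta\phi(t)$ (trials judged *trust* vs
*untrust*), pointwise over post-stimulus time:

$$C(t) = \left|\,\overline{\Delta\phi}_{\mathrm{trust}}(t)
              - \overline{\Delta\phi}_{\mathrm{untrust}}(t)\,\right|.$$

If the observer's judgment modulates hemispheric frequency, $C(t)$ grows
with $t$; its regression slope, divided by $2\pi$, is the
frequency-divergence estimate in Hz.

## The balanced-resampling null

Any nonzero $C(t)$ could reflect generic trial-to-trial variability rather
than the judgment. The reference for significance is therefore a null
distribution built per observer: the trials are randomly partitioned into
two equal halves, *balanced* so that each half carries (as nearly as
possible) equal numbers of trust and untrust trials, and the same statistic
is computed between the halves. Repeating this 1,000 times (200 in the
scaled-down validation studies) yields a pointwise distribution whose
2.5th–97.5th percentiles form the 95% envelope. `exceedance()` reports
where the real-label profile escapes the envelope; contiguous runs are
summarized as significant intervals.

Two readings of "escapes" exist and the package exposes both:

* `sides = "above"` (default) flags profile values above the upper bound —
  the natural significance reading for a nonnegative statistic, and the one
  used for interval reporting.
* `sides = "outside"` flags values outside the two-sided interval — the
  correct reading for calibration checks, because an exchangeable statistic
  falls outside a 95% interval about 5% of the time but above its upper
  bound only about 2.5%.

Our calibration study (250 seeded replicates of a single observer with the
paradigm's 484 trials, 200 resamples each) measured an outside rate of
5.5%, i.e. the engine is calibrated at the nominal level. Two caveats are
worth recording. First, at much smaller trial counts (tens of trials) the
balanced constraint couples the resample partitions to the real label
split and the rates drift upward; calibration statements in this package
are therefore made at the per-observer study scale. Second, the
cohort-level envelope (null profiles averaged across subjects per resample
index before taking percentiles) is *conservative* at a 23-subject scale —
averaging absolute-valued statistics concentrates both the real statistic
and the null — so cohort-level exceedance understates, never overstates,
significance.

## The synthetic cohort generator

No real recordings ship with the package; every validation runs on
synthetic cohorts with known ground truth, built by `simulate_subject()` /
`simulate_cohort()`. The generator emulates the paradigm's structure:

* 11 sessions × 44 trials per observer (22 spontaneous, 11 instructed-lie,
  11 instructed-truth in the behavioral tables), trust/untrust labels
  balanced to within one trial; 23 observers per cohort by default;
* epochs of −500…3000 ms around stimulus onset, natively 500 Hz (a
  parameter; the heavy validation studies generate at 100 Hz directly,
  which is the analysis rate after decimation anyway);
* Gaussian-kernel evoked components — positive P100 (~100 ms), negative
  N170 (~195 ms), positive P300 (~275 ms) on posterior channels — with a
  multiplicative right-hemisphere gain (default 1.3 on P4/P8/PO4/O2) that
  reproduces the classic right-lateralized sign pattern: P7−P8 window means
  negative for positive components, O1−O2 positive for the negative N170;
* background activity per channel: 1/f-shaped noise (exponent 1, 5 µV RMS),
  an alpha rhythm (10 Hz, 4 µV) at non-target channels, and white sensor
  noise (2 µV);
* the injected effect: at the target pair (CP1–CP2), a narrow-band
  oscillation at $f_0 = 10$ Hz whose frequency steps phase-continuously at
  onset (800 ms) to $f_0 \pm \Delta f/2$ — left high/right low on trust
  trials, mirrored on untrust trials. The within-condition
  interhemispheric difference is thus $\Delta f$, and the conditioning
  statistic diverges at $2\Delta f$ (the two conditions pull in opposite
  directions). `condition_divergence()` estimates $\Delta f$ directly as
  half the difference of the trust- and untrust-mean phase-shift slopes.

The 800 ms onset mirrors the post-stimulus window in which the reference
analysis found sustained effects; it is a modeling choice, as is the
Gaussian shape of the evoked kernels. The generator does not emulate
artifacts (blinks, motion), volume-conduction correlations between
channels, or non-stationary background power — so passing recovery tests
demonstrates correctness of the estimators, not robustness to everything
real EEG can do.

## Study configurations and what they show

Two pre-sized configurations (both 100 Hz, minimal CP1/CP2/Cz montage, no
evoked components) are exported because the validation studies and the
acceptance script share them:

* `divergence_study_params()` — oscillation 5 µV against a weak background
  (0.75 µV 1/f + 0.5 µV noise), $\Delta f = 2.18$ Hz (the reference
  effect scale). With the oscillation dominant, the mean recovered
  divergence over a 23-subject cohort is exact to well under 15%, and
  recovery holds across $\Delta f \in \{0.5, 1, 2, 3\}$ Hz. The high SNR
  is deliberate: the instantaneous phase of a broadband mixture advances
  at a power-weighted compromise of its components' frequencies, so a
  divergence carried by a minority-power component is recovered attenuated
  by roughly that component's power fraction (about ×0.23 at the realistic
  default background). The recovery study validates the estimator in the
  regime where the parameter is identifiable; the attenuation itself is a
  property of broadband phase, shared by any full-band Hilbert analysis.
* `interaction_study_params()` — oscillation 1.6 µV against the realistic
  background. This amplitude was scanned once (1.0–1.75 µV) and frozen so
  that the 2 (electrode) × 2 (condition) repeated-measures interaction on
  spectral centroids lands near the reference effect size (observed
  partial $\eta^2 \approx$ 0.23–0.35 across seeds) with detection power
  above 80% at $n = 23$, while the identical battery run on the random
  balanced halves (control1/control2) rejects at the nominal 5%.

With $\Delta f = 0$ the observed (real-label) conditioning slope and the
control slope (per-observer median over null-resample slopes) are
statistically indistinguishable: across 20 seeded null cohorts the paired
repeated-measures comparison retains the null in ≥90% of replicates, with
approximately uniform p-values.

## Preprocessing choices

The default chain is band-pass → decimate → baseline-correct →
re-reference to Cz.

* **Filtering.** Zero-phase (forward–backward) Butterworth, realized as a
  cascade: order-4 high-pass at 1 Hz — kept gentle because steep high-pass
  filtering distorts slow ERP waveforms — and order-8 low-pass at 49 Hz,
  steep enough to suppress a 60 Hz tone to under 5% residual RMS and to
  double as the anti-alias filter before decimation. Zero-phase
  realization is essential: phase distortion would corrupt the Hilbert
  analysis directly.
* **Decimation.** 500 → 100 Hz by keeping every 5th sample; the band-pass
  has already removed energy above the target Nyquist. A standalone
  `downsample()` applies its own protective low-pass unless told otherwise.
* **Baseline.** Mean over [−500, 0) ms subtracted per trial and channel;
  epoch time axes are half-open with samples at bin starts.
* **Reference.** Cz subtracted from every channel (Cz retained as a zero
  channel). Left-minus-right differences are invariant to any common
  reference, and the tests assert this; per-electrode phase is *not*
  reference-invariant, so the reference is fixed to Cz throughout, and the
  order (baseline before re-reference) is immaterial for difference-based
  results.
* **Hilbert transform.** Applied to the full 3,500 ms epoch, without
  tapering, so edge effects sit in the baseline and the final samples;
  edge-sensitive checks exclude 10% margins. Phase-shift profiles are
  restricted to [0, 3000) ms and re-zeroed at stimulus onset, so the slope
  rather than an arbitrary offset carries the effect.

## Statistics

* Per-window ERP contrasts (30 non-overlapping 100-ms windows tiling
  [0, 3000) ms, per channel) use the within-subject two-level design, for
  which the repeated-measures F is exactly the squared paired t; the
  implementation exploits the identity (vectorized across 870
  channel-window cells) and reports uncorrected and Holm-corrected p.
* `compare_slopes()` and the centroid battery fit genuine
  `aov()` models with subject error strata, so the F = t² identity is
  *checked* between independent code paths in the tests rather than assumed
  everywhere.
* Spectral centroids use a one-sided periodogram on the fixed 0–50 Hz /
  0.5 Hz grid, obtained by zero-padding the 800–2000 ms window (120
  samples at 100 Hz) to 200 samples. The grid is finer than the window's
  native 0.83 Hz resolution; this is an interpolation, stated as such.
  Scaling satisfies Parseval (power × bin width sums to the mean square).
  Per-trial centroids are averaged within subject and condition (rather
  than computing one centroid of an averaged spectrum); the two orders
  differ only through trial-level skew, and the per-trial order keeps the
  control entries (means over balanced half-partitions) exactly comparable.
* Tukey-HSD simple effects come from `emmeans` on the fitted `aov`;
  Cohen's d for the crossover contrast is the mean/SD of the per-subject
  differences (so $t = d\sqrt{n}$).
* Degenerate inputs error early and by name: all-zero signals have no
  phase, all-zero spectra no centroid, bands outside Nyquist name the
  bound, missing channels name the pair.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run, per invocation: one
23-subject recovery cohort; 20 null cohorts of 23 subjects with 200
resamples each; 200–250 single-observer calibration replicates (200
resamples each); 25 (tests) to 40 (acceptance script) interaction cohorts
of 23 subjects (50 resamples for
the control entries); plus fast structural and closed-form checks. These
sizes were chosen so each study's Monte-Carlo error is small relative to
the band being asserted (e.g. SE ≈ 0.7 percentage points for the
calibration rate).

## Known limitations

* The generator's effects are additive and narrow-band; real EEG mixes
  sources across channels, so recovered effect sizes on real data will be
  attenuated relative to the injected ground truth (see the SNR discussion
  above).
* The pointwise envelope is not family-wise corrected; contiguous-interval
  reporting mitigates but does not remove multiplicity. Interval onsets
  should be read as descriptive.
* Signed slopes are retained everywhere (profiles of an absolute-valued
  statistic can still regress negative under noise); summaries report the
  signed mean.
* ICA-grade artifact rejection is out of scope; the pipeline assumes clean
  epochs.
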