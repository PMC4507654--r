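---
title: "Estimating blood pressure from the oscillometric waveform envelope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from the oscillometric waveform envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

An automated cuff device inflates above systolic pressure and deflates
linearly while a pressure sensor records the cuff pressure. Superimposed on
the deflation ramp are small heart-beat-locked oscillations whose amplitude
grows to a maximum and decays again: plotted against cuff pressure, these
amplitudes form the *oscillometric waveform envelope* (OWE). The cuff
pressure at the envelope maximum is taken as the mean arterial pressure
(MAP), and the classical *maximum amplitude algorithm* (MAA) places systolic
and diastolic pressure (SBP, DBP) where the envelope has fallen to fixed
fractions — the *characteristic ratios*

$$\mathrm{SBPR} = \frac{A(\mathrm{SBP})}{\mathrm{MA}}, \qquad
  \mathrm{DBPR} = \frac{A(\mathrm{DBP})}{\mathrm{MA}},$$

where $A(\cdot)$ is the envelope and MA its maximum. Fixed ratios are a
population average; the true ratios vary with envelope shape (and hence
with arterial stiffness), which is the dominant error source of the MAA.
This package implements the variable-ratio alternative: regress the
per-recording reference ratios on features of the envelope, predict ratios
for unseen recordings under cross-validation, and invert the predicted
ratios on each recording's own envelope.

## Pipeline

1. **Detrending.** The cuff signal is band-passed with a first-order
   0.5–5 Hz Butterworth filter applied forward and backward (zero phase,
   effectively second order). 5 Hz corresponds to a 300 beats/min ceiling,
   0.5 Hz removes the ramp. Edge transients are handled by odd reflective
   padding of 10 time constants of the low corner; filtering is done
   relative to the first sample (restored through the filter's DC gain) so
   the transient scales with the signal's excursion rather than its
   ~180 mmHg offset. Three padding time constants proved insufficient on a
   180→40 mmHg ramp (mmHg-scale edge error); ten bring it below 0.06 mmHg.
2. **Segmentation.** ECG R-peak annotations delimit cardiac cycles; each
   pulse's peak, bottom and two peak-to-trough heights are measured on the
   detrended waveform. The pressure coordinate of each pulse is read from a
   zero-phase 0.3 Hz low-pass of the raw signal, so the envelope's pressure
   axis is free of oscillation.
3. **Artifact rejection.** Two rules, applied jointly, flag movement
   artifact before envelope fitting: (i) on each of the four height series,
   a pulse whose relative deviation from the median of its two neighbours
   on each side exceeds 0.4, or whose height leaves the ±50% band around
   that median, is an outlier; (ii) intervals where the low-passed pressure
   *rises* faster than 1 mmHg/s for at least 0.2 s during deflation are
   artifact (deflation is monotone at −2 to −3 mmHg/s). The first and last
   pulse have no two-sided neighbourhood and are exempt from rule (i): under
   a steeply decaying envelope the one-sided median is biased and would
   false-flag them.
4. **Envelope.** One knot per clean pulse at (cuff pressure, amplitude,
   time); amplitude defaults to the mean of the two peak-to-trough heights
   (robust to residual baseline; raw peak mode available). A natural
   interpolating cubic spline over cuff pressure is scanned on a 0.1 mmHg
   grid and refined to locate MA and MAP; equal twin maxima resolve to the
   higher pressure, and an endpoint maximum raises a truncation warning.
5. **Features.** Ten envelope features: MA (`amp1`); time from envelope
   onset to the MA position (`dur1`) and total envelope duration (`dur2`);
   trapezoidal areas under the time-ordered knot envelope, total (`area1`)
   and split at the MA time (`area2`, `area3`); the shape ratios
   `ratio1 = dur1/dur2`, `ratio2 = area2/area1`, `ratio3 = area3/area1`;
   and the MAA MAP estimate (`map_maa`). By construction
   `area1 = area2 + area3` and `ratio2 + ratio3 = 1`. Durations and areas
   use the time axis (deflation is near-linear, so the pressure axis is
   proportional); a pressure-domain mode is a trivial re-parameterisation
   of the knot table.
6. **Models.** Separate models predict SBPR and DBPR from chosen features:
   fixed ratios (training-set means, the MAA), ordinary least squares
   (QR-based, matching the normal equations on well-conditioned input), or
   linear ν-SVR (LIBSVM via **e1071**; features standardised internally,
   primal weights returned on the original scale). Predicted ratios are
   clipped to (0.05, 1] before inversion; clipping is reported. Ratio
   inversion brackets the crossing nearest MAP on the proper limb and
   bisects to 0.001 mmHg.
7. **Evaluation.** Bland–Altman mean and n−1 SD of (reference − estimate),
   cumulative percentages within 5/10/15 mmHg (inclusive boundaries), the
   BHS letter grade, and the AAMI criterion (|mean| ≤ 5 mmHg and SD under a
   tabulated limit; the mean is rounded *up* to the next tabulated 0.5 mmHg
   step, the conservative reading of the discrete table).

## Feature selection

All 55 subsets of one or two features are scored by the cross-validated SD
of SBP differences (4 folds, grouped by subject so no subject straddles
folds). Sequential forward floating selection then starts from the best
pair: add the best feature, then conditionally drop features while that
improves the criterion. A step is accepted only if it improves the
criterion by more than 10% (relative). This threshold is deliberately
coarse: a cross-validated SD carries a relative sampling error of roughly
$1/\sqrt{2n}$ (about 11% at $n = 40$), and with eight uninformative
candidate features the best *chance* improvement exceeded several percent
in the majority of simulated cohorts — a hair-trigger threshold would grow
the feature set on noise. Ties in the exhaustive ranking break toward fewer
features, then lexicographic names.

## The simulator

Real cuff recordings with expert reference scores are not distributable, so
the package ships a seedable simulator that emulates the acquisition
protocol: linear deflation 180→40 mmHg at 2–3 mmHg/s sampled at 1 kHz,
raised-cosine pulses (0.35 s) at a per-recording heart rate of 60–90
beats/min with R-peaks emitted as annotations, additive white sensor noise
(default 0.02 mmHg), and injectable artifacts. The envelope is a two-sided
generalized Gaussian in cuff pressure with shape exponent 1.5, maximum
1.5–3 mmHg at a MAP of 75–94 mmHg, and total width 50 mmHg split by an
asymmetry parameter $a \in [0.35, 0.65]$ into high- and low-pressure side
widths. The true ratios are linear in the asymmetry
(SBPR $= 0.75 - 0.5a$, DBPR $= 0.45 + 0.5a$, Gaussian link noise,
default SD 0.01), and SBP/DBP are *placed* where the envelope attains
SBPR·MA and DBPR·MA, so simulator ground truth and envelope are exactly
consistent; draws whose implied pressures leave 70–133 / 42–88 mmHg are
rejected. With the exponent-1.5 tails, `ratio2` is approximately the drawn
asymmetry, which gives regression models a recoverable signal — mirroring
the physiological claim that envelope shape carries the ratio information.
The shape exponent matters for realism of the screen: a pure Gaussian
(exponent 2) decays so fast far from MAP that even a noise-free envelope
violates the 0.4 neighbour rule in the extreme tails.

Movement artifacts are reduced to four signal-level archetypes — slow
pressure bump, single-pulse amplitude spike, broadband oscillation burst,
and cuff release — covering the protocol movements (arm lifts and bends,
tapping, squeezing, shaking, cuff removal) at the level at which they
appear in the pressure signal. Artifact magnitudes are not quantified in
the source protocol; defaults (e.g. ×1.8 spikes, +8 mmHg bumps) are chosen
so that contamination visibly degrades fixed-ratio estimates, making the
before/after-removal comparison reproducible in direction only.

What the simulator does *not* emulate: beat-to-beat pulse-shape and
heart-rate variability, respiratory modulation, nonlinear cuff mechanics,
Korotkoff sounds, and real artifact morphology. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions and
directional robustness to artifact, not clinical accuracy on human data.

## Numerical notes

* The forward-backward first-order band-pass has $|H|^2 \approx 0.90$–$0.95$
  at the pulse fundamental: every measured amplitude carries a common gain
  slightly below one. All characteristic ratios, MAP, and the shape features
  are invariant to this gain; only `amp1` and the areas inherit it. Tests
  compare envelope *shape* after dividing out the fitted gain.
* The 0.3 Hz baseline retains the sub-0.3 Hz mean of the pulse train, a
  bias of up to ~0.5 mmHg on the envelope's pressure axis (largest where
  pulses are largest). It is well below the accuracy targets and shared by
  any implementation that low-passes the composite signal.
* The outlier screen is not strictly idempotent at artifact boundaries: a
  spike's filtered footprint spills into the adjacent beats' shared troughs,
  so after removal a second pass may flag a direct neighbour of a removed
  pulse — never a pulse away from the footprint.
* Degenerate inputs: envelope fitting requires ≥ 4 knots with distinct
  pressures (duplicates within 0.05 mmHg are merged by averaging);
  evaluation outside the knot domain is an error; a ratio the truncated
  envelope never reaches raises an error naming the failing limb; ratio 1
  degenerates to MAP.
* `fit_nusvr` defaults follow the base-2 reading of the published
  settings, $C = 2^{14.49}$, $\nu = 2^{-1.89} \approx 0.27$ (a literal
  $\nu = -1.89$ is outside $(0,1]$, while the stated search ranges
  $[-20, 20]$ and $[-20, 0]$ are natural as exponents). At this large $C$
  LIBSVM may report reaching its iteration cap; solutions remain usable,
  and both parameters are overridable.

## Problem sizes

The test suite runs cohorts of 12–50 recordings for pipeline checks, a
200-recording cohort for the fixed- versus variable-ratio comparison,
50 spiked noise-free recordings for artifact-removal efficacy, and 20
feature-level cohorts of 40 recordings for selection; `scripts/acceptance.R`
regenerates the 200- and 50-recording experiments from scratch under a
caller-supplied seed. These sizes give stable Bland–Altman statistics from
fully synthetic data while keeping a complete run in the minutes range.

## Limitations

The regression and selection machinery is validated on data whose
ratio-feature link is linear by construction; on real cohorts the link need
not be linear, and reference scores carry observer error that the simulator
represents only as Gaussian link noise. Subject-level effects are limited
to grouping (four recordings per simulated subject share a fold but are
otherwise independent draws, unlike repeated measurements of one arm).
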