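---
title: "Methods: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomap)
```

This vignette records the scientific model behind `cardiomap`, the
estimators it uses, the defaults it ships with and why, and the
boundaries of what its synthetic validation does and does not
demonstrate.

## The measurement model

A fluorescence movie from an optically mapped cardiomyocyte monolayer is
a stack $F(t, y, x)$ in arbitrary units (a.u.), acquired at a known
frame rate (typically 100 fps) and pixel pitch. The dye signal tracks
membrane potential (voltage dyes) or cytosolic calcium (calcium dyes):
each spontaneous beat appears as a fast upstroke followed by a slower
recovery toward the diastolic level. The analysis treats the ROI-mean
trace as the unit of rhythm and transient analysis, and the per-pixel
stack as the substrate of activation mapping. Intensities are never
rescaled on input: diastolic baseline fluorescence is itself a reported
metric, so the absolute a.u. level must survive the pipeline
(detrending re-adds the mean of the removed baseline for the same
reason).

## The waveform template and its closed-form durations

The simulator composes recordings from a five-parameter template: the
signal rests at baseline $F_0$, ramps linearly to $F_0 + A$ over the
upstroke time $t_{up}$, then repolarizes as

$$F(\tau) = F_0 + A\,(1 - (\tau/\tau_r)^p), \qquad \tau \in [0, \tau_r],$$

clamped at $F_0$ afterwards. The duration at recovery fraction $x$ is

$$D_x = t_{up} + \tau_r\, x^{1/p},$$

which `solve_template()` inverts in closed form for any two target
durations. This is the load-bearing design decision of the package: a
kinematic (template-superposition) generator makes the ground truth
*exact* — every configured APD/CaTD, beat time, and wavefront speed is a
known number rather than itself an estimate, so accuracy claims about
the pipeline are parameter-recovery statements. A reaction–diffusion
model would be more biophysical but would forfeit that property.

The exponent $p$ controls the repolarization shape: $p > 1$ back-loads
recovery (plateau then fast phase-3 drop, the action-potential-like
regime), $p < 1$ front-loads it (fast early decay with a long tail, as
in slow calcium reuptake). Both regimes occur when templates are solved
for published duration pairs, and both are exercised in the tests.

When successive beats arrive before repolarization completes, the next
upstroke starts from the instantaneous signal value. This keeps the
trace continuous and mimics real rate-dependent truncation. A
consequence worth knowing: in a sustained fast rhythm, beats after the
first are measured against their own elevated pre-upstroke baseline and
reduced amplitude — which is exactly what per-beat "percent return
toward baseline" semantics imply, and why truncated beats carry a
censoring flag and are excluded from duration means.

## Rhythm scripting, propagation, noise

Inter-beat intervals are Gamma-distributed with mean $1/f$ and a
directly specified coefficient of variation (`jitter_cv`), giving
strictly positive intervals and a one-knob irregularity control.
Quiescent episodes delete scripted beats; tachyarrhythmic segments
override the local rate; early afterdepolarizations (EADs) are additive
Gaussian bumps of height $\delta A$ placed where the template has
recovered the scripted fraction of its amplitude. The default bump
half-width is $\max(0.025\ \mathrm{s},\ 0.05\,\tau_r)$: wide enough to
be resolvable at 100 fps, narrow relative to the repolarization span.

Wavefronts are kinematic delay fields: planar (delay linear along a
direction), target (radial from an origin), or an Archimedean-spiral
activation-time field for the rotating pattern — sufficient to exercise
conduction-velocity estimation and heterogeneity, with no claim to
re-entry biophysics.

Noise is additive white Gaussian; the default `noise_sd = amplitude/20`
states the working assumption of peak SNR ≈ 20 for these preparations —
a config knob, not a claim about any particular camera. Photobleaching
is a monoexponential additive drift of the baseline.

## Estimators

**Beat detection.** Events are excursions of a Savitzky–Golay
first-derivative estimate above
$\max(0.2 \cdot \max \dot F,\ 8\,\widehat{\sigma}_{\dot F})$, where
$\widehat{\sigma}_{\dot F} = \mathrm{mad}(\Delta \dot F)/\sqrt 2$ is a
high-frequency noise scale that is immune to the derivative's slow
signal content. The fraction-of-max term adapts to signal strength; the
noise floor guarantees that beat-free traces yield no events. The
derivative window defaults to 30 ms for voltage and 90 ms for calcium,
matched to each dye's upstroke kinetics. Events are refined to sub-frame
precision by parabolic interpolation of the derivative peak, merged
within a 100 ms refractory window (keeping the larger), and boundary
artifacts within the filter half-window of the trace edges are dropped.

**Activation onset.** The onset is the intersection of the
maximum-upstroke tangent with the baseline level (the standard
dF/dt-max convention). The last filter half-window before the peak is
excluded from the slope search when the upstroke is long enough,
because polynomial derivatives overshoot at the peak corner and the
tangent back-projection amplifies that error.

**Baseline and peak.** The baseline is the median of a 50 ms window
ending just before the onset, computed twice (the second pass anchored
to the refined onset). The peak is the median of the three samples at
the discrete maximum: exact on plateaus, and robust both to the
localized smoothing overshoot at sharp upstroke corners and to the
noise-maximum bias of a plain max.

**Duration crossings.** $D_x$ is the first linearly interpolated time
after the peak at which the signal falls below $\mathrm{peak} - x\,\Delta F$
— a definition that guarantees $D_{30} \le D_{80} \le D_{90}$. On
shallow decays the first noise dip precedes the true crossing, so when
at least five samples lie within $\pm 0.07\,\Delta F$ of the level the
crossing is refined by a linear fit of that band; on steep crossings
the band is too short and plain interpolation (already sub-frame
accurate there) is kept. The band is narrower than the gap between the
90% level and the diastolic plateau, so the post-repolarization plateau
cannot contaminate the fit.

**EAD detection.** Secondary deflections are scored with Mexican-hat
(negative second-derivative-of-Gaussian) matched filters at a few time
scales, normalized so the response to a matched bump equals its height.
A deflection counts when its response exceeds both $\delta \cdot \Delta F$
(default $\delta = 0.10$) and five times the robust spread of that
scale's response over diastolic samples. Scales whose support does not
fit inside the beat's 30–90% repolarization span are excluded — coarser
scales respond to the decay's own concavity, not to a superimposed
deflection. A practical limitation follows: at 100 fps with ~20 ms
voltage upstrokes and SNR 20, voltage-trace EADs sit at the edge of
resolvability, and EAD assessment is most reliable on calcium
recordings (whose kinetics are slow relative to the frame interval).
The validation cohorts therefore script EADs on calcium traces.

**Conduction velocity.** Per-pixel activation times come from the same
sub-frame derivative-peak estimator after 5×5 spatial binning (standard
optical-mapping practice; on a planar or gently curved front binning
does not displace the wavefront but suppresses the per-pixel timing
noise that otherwise biases $1/\|\nabla t\|$ low at high speeds).
Activation time is then fitted by a plane over sliding 5×5
neighborhoods (quality pixels only); neighborhoods with near-zero
gradient or $R^2 < 0.9$ are excluded, and the recording's CV is the
median of local speeds (the mean is also reported; the median resists
wavefront-collision outliers). By default CV comes from the first fully
captured beat, with a 50 ms guard before the next beat's onset so its
smeared upstroke cannot capture the derivative maximum.

**Rhythm rules.** The published phenotypes are categorical, so
classification is deterministic rules over measured evidence, all
thresholds configurable and recorded in every assessment: tachycardia
above 2.0 Hz (well above normal spontaneous rates but below no
physiological fast rhythm of interest; when a reference cohort is
supplied the rule becomes 2.5× its mean rate, capturing "abnormal
increase relative to control"), bradycardia below 0.2 Hz, quiescence
for gaps beyond $\max(5\ \mathrm{s},\ 3\times$ median interval$)$ — the
relative guard keeps slow-but-regular rhythms from being called
arrested — and irregularity for interval CV above 0.20 with at least 5
beats, computed on beating intervals only (silent gaps are quiescence
evidence, not irregularity evidence). Delayed or premature single
beats express themselves through the interval CV; no bespoke detector
is attempted for them.

**Statistics.** Normality is tested per group by Kolmogorov–Smirnov on
standardized residuals (sample mean and SD plugged in — the common
applied reading; this variant is conservative, which only makes the
parametric branch harder to enter). Homoscedasticity uses the F-test —
for more than two groups, the max-vs-min variance pair with Bonferroni
adjustment. The parametric branch is one-way ANOVA with Tukey HSD; the
nonparametric branch Kruskal–Wallis with pairwise Mann–Whitney; both
report raw and Bonferroni-adjusted pairwise p-values, with significance
flagged at the adjusted level, since combining Tukey with an additional
Bonferroni pass is ambiguous in common usage and emitting both avoids
guessing. The chi-square incidence test uses no continuity correction
by default (configurable, logged). The acceptance suite verifies the
whole decision tree's type-I error on null Normal data lies in
[0.03, 0.07] at $\alpha = 0.05$ over 2,000 simulations.

**Fridericia correction** divides each beat's D80 by the cube root of
its own preceding interval; per-beat correction is the standard form
for rate-normalization formulas and coincides with mean-rate correction
for regular rhythms. First beats (no preceding interval) are excluded
from corrected means.

## Validation design and problem sizes

Acceptance is by parameter recovery: templates and propagation models
are configured at the published group values (wild-type conduction
velocity 14 cm/s and Fabry-disease 8.5 cm/s; rates 0.67 and 1.28 Hz;
corrected APD80 0.17 s; APD triangulation 0.10 s; CaTD80 1.08 s; CaT
triangulation 1.172 s; diastolic baseline 0.46 a.u. with amplitude
0.15), cohorts are simulated at SNR 20, and the pipeline must return
those numbers. Sizes used: 10 recordings of 64×64×1000 frames for each
CV cohort, 26 thirty-second traces for frequency, 20 traces for each
APD quantity, 8 for each calcium quantity, and 16/36/40-recording
cohorts for the arrhythmia-incidence counts — large enough that cohort
means are stable to well within the tolerances, small enough that the
whole run completes in a few minutes on one CPU.

Two nuisance parameters are not stated alongside the published values
and were fixed once on physiological grounds: the calcium cohorts beat
at 0.4 Hz (the published pre-treatment Fabry rate of 0.07 Hz would give
only ~2 beats per 30 s trace; 0.4 Hz keeps every CaTD90 uncensored
while remaining in the spontaneous range), and the CaT-triangulation
template uses CaTD30 = 0.55 s (a typical early-recovery time for these
dyes; the published CaTD80 and triangulation values cannot be realized
simultaneously by a single template without an extreme shape exponent,
so each quantity gets its own physiologically shaped cohort).

## What passing tests do and do not show

The generator shares the analysis's structural assumptions: transients
are exact template copies, noise is white and Gaussian, bleaching is
monoexponential, wavefronts are kinematic. Recovery under these
conditions demonstrates that the estimators are unbiased and correctly
calibrated *for the signal model they assume*; it does not probe motion
artifacts, spatially correlated noise, dye internalization, cell-scale
heterogeneity, wave collisions, or true re-entry. The rotating pattern
exercises gradient heterogeneity, not rotor dynamics; rhythm-level
arrhythmia flags are the intended scope. Ratiometric calibration to
absolute calcium concentration is out of scope, which is why upstroke
comparisons default to the amplitude-normalized slope.
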