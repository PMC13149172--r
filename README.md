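# cardiomap

Optical-mapping electrophysiology analysis for spontaneously active
cardiomyocyte syncytia, with a ground-truth synthetic-syncytium simulator.

Human iPSC-derived ventricular cardiomyocyte monolayers, imaged with
voltage-sensitive (e.g. Fluovolt) or calcium-sensitive (e.g. Calbryte)
dyes, beat spontaneously and propagate activation wavefronts across the
field of view. Disease models — such as α-galactosidase-A-null lines
modeling Fabry disease — are characterized by comparing cohorts of these
functional syncytia on a standard panel of metrics: spontaneous
activation frequency, action-potential and calcium-transient durations,
conduction velocity, and arrhythmia incidence. `cardiomap` implements
that analysis end to end, for people who run such cohorts and for people
who need to validate the analysis itself.

## What it computes

**Per-beat transient metrics.** For each detected beat of a fluorescence
trace *F(t)*: diastolic baseline *F_d* (median of the pre-upstroke
window), amplitude *ΔF* = peak − *F_d*, maximum upstroke rate
(dF/dt)_max (raw and normalized by *ΔF*), and durations at recovery
fraction *x*,

> D_x = first time after the peak with F < peak − x·ΔF, measured from
> the activation onset (dF/dt-max tangent convention),

giving APD30/APD80/APD90 for voltage and CaTD30/CaTD80/CaTD90 for
calcium, plus triangulation D90 − D30 and the Fridericia rate correction
D80 / RR^(1/3) with the preceding inter-beat interval RR.

**Conduction velocity.** Per-pixel activation times (sub-frame
derivative-peak timing after light spatial binning) are fitted by local
planes over sliding 5×5 neighborhoods; the local speed is 1/‖∇t‖ and the
recording's CV is the median over quality-controlled neighborhoods.

**Rhythm classification.** Deterministic rules with configurable,
logged thresholds: tachyarrhythmia (rate > 2 Hz, or > 2.5× a reference
cohort's rate), bradyarrhythmia (< 0.2 Hz), quiescence (silent gap >
max(5 s, 3× median interval) or no beats), beat irregularity
(inter-beat-interval CV > 0.20), and early afterdepolarizations
(matched-filter detection of secondary deflections ≥ 10% of the beat
amplitude during 30–90% repolarization).

**Cohort statistics.** The standard decision tree: Kolmogorov–Smirnov
normality per group and an F-test for variance homogeneity choose
between one-way ANOVA + Tukey and Kruskal–Wallis + pairwise Mann–Whitney
with Bonferroni correction; arrhythmia incidence uses the Pearson
chi-square test. Results are mean ± SEM with a full audit trail.

**Synthetic syncytia.** `simulate_recording()` generates movies
kinematically from a five-parameter waveform template whose durations
have the closed form D_x = t_up + τ_r·x^(1/p) — so the ground truth
(beat times, durations, conduction speed, baseline, amplitude, scripted
arrhythmias) is exact, and every stage of the pipeline is testable by
parameter recovery.

## Worked example

Simulate a wild-type-like syncytium (0.67 Hz, planar wave at 14 cm/s,
64×64 px, 100 fps, peak SNR 20) and analyze it:

```r
library(cardiomap)

cfg <- sim_config(height = 64, width = 64, pixel_pitch = 0.01,
                  duration = 10,
                  rhythm = rhythm_script(0.67, jitter_cv = 0.03),
                  propagation = propagation_model("planar", 14),
                  seed = 42)
rec <- simulate_recording(cfg)
res <- analyze_recording(rec$movie)
res$summary[, c("n_beats", "frequency", "d80c", "tri", "cv_median", "labels")]
#>   n_beats frequency      d80c        tri cv_median labels
#> 1       7  0.671386 0.1897733 0.05690103  14.00977 normal
res$assessment
#> <rhythm_assessment> normal
#>   f=0.671 Hz, IBI CV=0.0333, longest gap=1.58 s, EADs=0, beats=7
```

The analysis recovers the scripted 0.67 Hz rate, the 14 cm/s conduction
velocity, and a normal rhythm with no arrhythmia flags; `d80c` is the
Fridericia-corrected APD80 in seconds and `tri` the APD triangulation.
`run_simulate()` / `run_analyze()` do the same for whole cohorts on
disk (TIFF or HDF5 movies + CSV/JSON outputs), and
`inst/cli/cardiomap.R` exposes them as a small command line.

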