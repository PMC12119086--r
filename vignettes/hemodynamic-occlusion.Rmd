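---
title: "Modeling and quantifying hemodynamic occlusion in two-photon imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying hemodynamic occlusion in two-photon imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoccl)
```

## The occlusion model

Blood absorbs both the excitation and the emission light of a two-photon
microscope. Vessels lying inside the collection cone between the objective
and a labeled neuron therefore modulate the measured fluorescence as they
dilate and constrict, even when the neuron's true fluorescence is constant.
`hemoccl` models this to first order: if `A(t)` is the effective vessel
cross-section and `A0` its baseline, the measured fluorescence is

    F_meas(t) = F_true(t) * clamp(1 - k * (A(t) - A0) / A0,  0.05, 20)

with a dimensionless gain `k >= 0`. Dilation (`A > A0`) darkens the
measurement, constriction brightens it. The linear form is a first-order
(Beer–Lambert) linearization in the relative cross-section change; no
saturating functional form is claimed by the underlying physiology
literature, so the clamp bounds `[0.05, 20]` are a numerical guard, not a
physical statement — they only bind under parameter settings far outside
the defaults.

The geometric reach of the artifact follows from the collection cone: a
neuron at depth `d` under an objective with half angle `theta` collects
light through a surface circle of diameter `2 * d * tan(theta)`
(`occlusion_footprint()`); at 500 µm and 45° that is 1 mm, so *any* surface
vessel within a millimeter can contribute. `effective_frame_rate()` encodes
the acquisition timing: a 60 Hz resonant scanner interleaved over 4 piezo
planes revisits each plane at 15 Hz, the sampling rate assumed throughout.

## The forward simulator

`scene_config()` + `simulate_behavior()` + `simulate_vessel_dynamics()` +
`render_frames()` generate a complete synthetic session with lossless
ground truth, so every downstream stage can be tested against known truth.

**Behavior.** Running speed is a two-state (stationary/locomoting)
semi-Markov process with exponential dwell times (defaults 20 s and 15 s),
bout speed ~10 cm/s with slow multiplicative wobble, smoothed by a 0.5 s
boxcar so bouts ramp on and off. The paper-style visuomotor contexts are
explicit: in `closed_loop` visual flow equals running speed, in `open_loop`
it is an independently generated bout trace (a replay), in `dark` it is
zero. Gratings (default 2 s every ~15 s) and optogenetic light pulses (1 s
every ~20 s) are scheduled with jitter; 1 s visuomotor mismatches are
placed only at frames where the smoothed speed stays at or above the
0.25 cm/s locomotion threshold over the whole −0.5 s to +1 s validity
window, so generated mismatches are valid by construction.

**Vessel dynamics.** `A(t) = A0 * (1 + sum of kernel-convolved event drives
+ noise)`, floored at 10% of `A0`. Each event kind has a signed
double-exponential kernel `a * (1 - exp(-t/tau_r)) * exp(-t/tau_d)`,
peak-normalized so its maximum equals the amplitude `a` (fraction of `A0`;
dilation positive). Defaults: locomotion onset −0.08 (constriction),
gratings +0.05, light pulses +0.10, mismatch −0.03, all with 0.5 s rise and
1–2 s decay. The additive noise term (SD 0.02 after 0.5 s smoothing)
emulates spontaneous vasomotion.

**Why these numbers.** With gain `k = 0.12`, a −8% locomotion constriction
produces a noise-free population response of about +1% ΔF/F₀ — the
magnitude scale reported for activity-independent GFP at locomotion onset,
and comparable to (only marginally smaller than) typical calcium-indicator
responses. The kernels' signs encode that vessels can dilate to stimuli and
constrict at locomotion onset depending on area; the defaults pick one such
regime rather than claiming universality.

**Rendering.** Each frame is background neuropil (level 10) plus soma disks
(radius 4 µm, level ~100, times the per-frame attenuation), with the vessel
drawn as a near-zero-intensity ellipse of instantaneous area `A(t)` at
fixed center and orientation, blurred by a Gaussian point-spread proxy
(σ = 1.5 px), scaled to photon counts (100 per intensity unit) for Poisson
shot noise, and optionally translated by integer rigid jitter. A
configuration whose vessel would leave the frame at maximal dilation is
rejected. The ground truth records soma geometry, per-frame fluorescence
and attenuation, the vessel area series, and every injected shift; with
noise off, the recorded truth reproduces each rendered frame exactly (a
tested invariant).

**What the generator does not emulate.** No optics-accurate 3-D PSF or
light transport, no hemoglobin oxygenation spectra, no brain-motion
kinematics beyond rigid translation, no z-motion, no neuropil structure or
labeled processes, no multi-plane rendering. Passing tests therefore
demonstrate correctness of the *analysis machinery* under a controlled
forward model, not that real recordings will show any particular effect
size.

## Extraction pipeline

Registration is integer-pixel and exhaustive: each frame's displacement is
the shift (within a search radius) maximizing Pearson correlation with the
reference (stack mean by default); ties break toward the smallest Euclidean
shift, then lexicographically; exposed pixels are filled with the frame
median. Subpixel registration is deliberately out of scope — the synthetic
contract only injects integer shifts.

ROI traces are plain pixel means (no neuropil subtraction). Slow drift is
removed with a running-percentile baseline: the 8th percentile over a
centered 66 s window (≈1000 frames at 15 Hz; a 62.5 s variant is a
parameter). Two numerical choices matter here. The percentile is the
left-continuous inverse ECDF (`quantile type = 1`, an order statistic), as
in standard percentile filters; this also keeps the property that the
baseline sits at or below the trace at ≥92% of frames. Windows are centered
and truncated at the recording edges; for even window lengths the extra
frame falls on the right.

ΔF/F₀ is scale-preserving: `F_c = F - baseline + mean(baseline)`,
`F0 = median(F_c)`, `dff = (F_c - F0) / F0`. Re-adding the baseline mean
keeps `F0` on the raw intensity scale; a non-positive `F0` is an error
naming the ROI. ΔF/F₀ is invariant under global gain changes (tested).

**Time conventions.** Frame `i` (1-based) covers `[(i-1)/rate, i/rate)`
seconds. A window `[t0, t1)` in seconds maps to the half-open 0-based
offset range `[floor(t0*rate), floor(t1*rate))`. All analysis windows below
use this mapping.

## Event analysis

A locomotion onset is a frame at or above 0.25 cm/s that stays at or above
threshold for the following 1 s, having been strictly below for the whole
preceding 1 s. The boundary convention (≥ at and after the onset, strict <
before) is a documented choice; the rule itself enforces a ≥1 s refractory
gap, so no extra refractory period is added. The same rule on visual flow
speed yields visual-flow onsets. Grating and opto onsets are flag rising
edges, not inferred. Mismatch onsets are kept only if speed stays at or
above threshold from −0.5 s to +1 s (0.12 cm/s available as the relaxed
variant for trigger-poor sessions).

Event-triggered analysis slices `[-pre, +post)` windows, drops incomplete
ones, and requires at least three surviving trials per ROI. Baselines:
−0.5…0 s, except −1…−0.5 s for locomotion (preparatory activity). Response
windows come in two named profiles: `responsiveness` (+0.5…+1.5 s for
locomotion/mismatch, +0.5…+2.5 s for the 2 s gratings) and `comparison`
(0…+2 s, gratings +0.5…+3 s). A neuron is responsive if a two-sided
one-sample t-test of its per-trial window means against zero gives
`p < 0.05`. Two-sidedness is a choice (the criterion is "different from
zero" with unstated sidedness); no multiple-testing correction is applied
across neurons because the downstream quantity is the raw fraction
responsive compared against the 5% chance line; that across-site comparison
uses a one-sample t-test of site fractions against 0.05 (the exact
site-level test is not pinned down by the source material — a documented
assumption).

Because mismatches only occur during locomotion, and locomotion itself
drives occlusion, mismatch responses are referenced to a random-trigger
null: triggers are drawn uniformly without replacement from frames
satisfying the same sustained-locomotion rule, excluding ±1 s around true
mismatches; repeating the population event-triggered average over many
trigger draws gives a per-bin 2.5th–97.5th percentile chance band. The
number of triggers per draw and the overlap-exclusion rule are package
choices (the source does not state them); the default trigger count is the
session's valid mismatch count, and at least 40 repetitions are required
for a usable 95% band.

## Hierarchical bootstrap

Neurons are nested in imaging sites, so SEs and tests resample sites with
replacement (as many as observed) and then neurons within each drawn site
(as many as that site has, preserving per-site sample sizes — a choice; the
alternative of a fixed pooled count ignores site sizes). The SE band is the
15.8th–84.2nd percentile interval (a 1-SD, 68% interval) of the replicate
means; defaults are 10,000 replicates for tests and 1,000 for plotted
curves. Trials are averaged per neuron before resampling — a two-level
scheme; a third trial level is not resampled. Condition comparisons
bootstrap each condition independently and report per-bin two-sided
sign-fraction p values `p = 2*min(frac<=0, frac>=0)`, floored at
`1/n_boot`, with significance at `p < 0.01` and no across-bin correction.

One implementation note: repetition-level datasets in the calibration
utilities are drawn from a single seeded RNG stream rather than from
per-repetition derived seeds; structured `set.seed` values produce
detectably correlated Mersenne–Twister streams, which biased a coverage
estimate before the switch.

## Vessel analysis

Cross-section estimation binarizes each frame of a (trial-averaged) video
at a single global threshold — the 0.5th percentile of all pixel
intensities in the video — takes the largest 8-connected below-threshold
component, and fits the ellipse with the same second central moments
(semi-axes `2*sqrt(eigenvalues)` of the pixel covariance with the 1/12
square-pixel correction); its area `pi*a*b` is the estimate. Components
touching the crop edge are flagged as possibly truncated; frames with no
below-threshold pixels return area 0 with a warning. Note the regime this
rule assumes: the pooled 0.5th percentile binarizes the *whole* lumen only
when the dark vessel occupies less than ~0.5% of the pooled video pixels
(or when noise scatters the dark mode); the test fixtures are built in that
regime, and the estimator is validated against a below-threshold
pixel-count oracle and against ground-truth dilation sequences.

Because low-contrast boundaries make thresholding fragile, the pipeline's
variance-explained numbers use the more robust lumen proxy: the mean
fluorescence of a fixed ROI fully contained in the vessel at rest. The
lumen itself is dark, so its signal is the point-spread tail of the
surrounding labeled tissue — it rises as the vessel constricts. The
default lumen ROI is the inscribed rectangle of the baseline ellipse at 0.9
scale: fully inside at rest, close enough to the wall to see it. Both the
vessel series and the neuronal signal are smoothed with a 0.5 s centered
moving average (width rounded to the nearest odd frame count, edges
truncated) before computing variance explained, `R² = cor(x, y)²`, either
on a −2 s to +6 s event window or over the entire recording. Zero-variance
inputs return `NA`. The Tukey-fence mask (`Q3 + 1.5*IQR` / `Q1 - 1.5*IQR`)
exists only for display-level omission, never for statistics.

## State-dependent correlations

Pairwise Pearson correlations of ΔF/F₀ between same-site neurons are
computed separately on stationary and locomoting frames (per-frame
threshold classification, no hysteresis and no peri-transition exclusion —
the source is silent on both), then averaged per neuron over its pairings.
A site needs at least 150 frames (10 s at 15 Hz) in each state; flat traces
propagate `NA` to their pairings. Pearson rather than rank correlation is
the field default for ΔF/F.

## Problem sizes and tolerances in the test suite

The suite validates against independent oracles at sizes chosen to keep a
full run around two minutes: onset detection against a brute-force rule
transcription on 1,000 random traces; registration against an exhaustive
SSD search on 64×64 stacks with ±2 px jitter; ellipse areas against pixel
counts on 256×256 videos; type-I calibration on 20 sites × 50 ROIs × 12
sham events (tolerance: 3 binomial SEs around 5%); bootstrap-band coverage
on 1,000 repetitions × 1,000 replicates (3 binomial SEs around the nominal
68.4%); and amplitude recovery of an injected 1.2% occlusion response
within 10% noise-free and 25% under Poisson noise with ~30 trials. The
amplitude-recovery scene uses a dim neuropil (level 2) so that the ROI's
constant neuropil contribution dilutes the soma signal by under 3%; with
the default neuropil level the dilution is itself a ~10% effect — a real
caveat for interpreting absolute ΔF/F₀ amplitudes from small ROIs.

## Known limitations

- The occlusion gain `k` is a free parameter; absolute artifact sizes in
  real data depend on vessel geometry, depth, and wavelength and must be
  calibrated per preparation.
- One vessel per scene; real fields of view integrate many vessels with
  heterogeneous kernels, which the per-soma attenuation hook supports but
  the default scene does not exercise.
- The threshold-based area estimator degrades sharply for vessels whose
  lumen is large relative to its crop or barely wider than the PSF; the
  lumen proxy is the robust alternative and is what the pipeline reports.
- Registration is integer-pixel and rigid; non-rigid tissue deformation
  around dilating vessels is explicitly out of scope.
- Onset-count monotonicity in the speed threshold holds for bout-structured
  traces but not for arbitrary ones (a trace hovering between two
  thresholds can gain an onset under the higher threshold); the detector
  implements the rule as stated rather than enforcing monotonicity.
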