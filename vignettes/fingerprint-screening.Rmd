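---
title: "Multidimensional fingerprint screening: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional fingerprint screening: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbscreen)
```

## The screening problem

Plant food supplements are complex pulverized mixtures, so detecting a
regulated plant inside one cannot rely on single marker peaks. The approach
implemented here treats the whole LC-DAD data cube of an injection —
absorbance indexed by wavelength and retention time — as a *multidimensional
fingerprint*. A handful of mutually uncorrelated detection wavelengths is
selected, the chromatograms at those wavelengths are aligned, concatenated
into one long feature vector per sample, and a PLS-DA model is trained to
separate samples that contain the target plant from blank botanical matrices.

The training design mirrors a spiked-trituration study: for each target plant,
11 blank matrices (one of them a lactose diluent) are each spiked at the five
mass ratios 1/20, 1/15, 1/10, 1/5 and 1/2 — so the plant makes up 5–50% of
the mixture — giving 55 triturations, plus the 11 unspiked blanks and one
pure reference injection: 67 records for a binary study, and
4 × 55 + 11 + 4 = 235 for the pooled multiclass study.

## The synthetic data generator

No public LC-DAD data accompany this study design, so `chromsim` generates
studies with the statistical structure the analysis assumes:

* **Peaks.** Each compound contributes a Gaussian peak in time
  (`retention_width` = sigma, default 0.9–1.4 s — typical sub-2-µm UHPLC
  peak widths) with a UV spectrum that is a non-negative sum of Gaussians in
  wavelength.
* **Mixing.** Absorbance is strictly additive (Beer–Lambert): a trituration
  at ratio *r* is `r × plant + (1 − r) × matrix`, pointwise. With zero noise
  this linearity is exact and is asserted by a test.
* **Shared chemistry.** Botanical supplements share much of their chemistry,
  so all matrices draw from a pool of 12 common constituents (each carried
  with probability 0.7 at a matrix-specific level); every matrix adds 2 and
  every plant 4 distinctive peaks. Distinctive retention centers sit on a
  0.10 min slot grid assigned without replacement, which guarantees each
  plant an identifying peak inside the fingerprint window that no matrix
  shares — the separability a real reference plant must have for the method
  to be applicable at all.
* **Co-elution.** A matrix's non-signature peaks co-elute with a randomly
  chosen plant peak with probability 0.6 (same retention slot, an unrelated
  spectrum). Co-elution is ubiquitous in real chromatograms and is the
  phenomenon that makes single-wavelength fingerprints ambiguous — without
  it, one channel could always separate the classes and comparing
  multiwavelength against 254 nm fingerprints would test nothing.
* **Disturbances.** Per-injection global retention jitter
  (`rt_jitter_sd = 0.02` min ≈ 0.5% of a mid-window retention time, the
  upper end of routine UHPLC stability), i.i.d. Gaussian detector noise
  (`noise_sd = 0.002` AU against peak heights of 0.3–1 AU) and a slow
  quadratic baseline drift (amplitude 0.01 AU). These magnitudes are package
  choices — the study conditions they emulate do not pin them — and they are
  deliberately large enough that alignment is necessary rather than
  cosmetic.

What the generator does **not** emulate: real UV spectra of the regulated
compounds, detector non-linearity and saturation, peak tailing and
asymmetry, pump pulsation, carryover, and extraction-efficiency
variability. The absence of detector non-linearity in particular shapes
what the end-to-end tests can show; see *Limitations*.

Grids default to 200–400 nm at 1 nm and 0–8 min at 0.05 s (9601 points).
The full 201-channel cube is only ever generated for the single reference
record used in wavelength selection; study cubes are simulated on the
selected wavelength grid, which is what the downstream pipeline consumes.

## Wavelength selection

The Pearson correlation between all channel pairs of the reference plant's
record forms a correlation map. The published procedure inspected such a map
visually; the deterministic replacement here seeds the selection with the
channel of maximal total signal and repeatedly adds the channel whose worst
absolute correlation to the current set is smallest, stopping at the 0.95
cutoff or at five channels. Absolute correlation is used because an
anti-correlated channel duplicates information just as a correlated one
does. Zero-variance channels are flagged and excluded — a flat channel would
otherwise look maximally orthogonal while carrying no fingerprint at all.
The same reasoning extends to channels that are merely *near*-flat: with
realistic detector noise, a channel outside the absorbing region (say the
400 nm tail) is noise-only, correlates with nothing, and would always be
"selected" while contributing no information. Candidates are therefore
required to span at least 5% of the seed channel's dynamic range
(`min_signal_frac`, 0 to disable), which keeps the selection inside the
absorbing region the way a visual colour-map inspection naturally would.
The pairwise (not merely adjacent-wavelength) cutoff is adopted since the
selection is meant to be orthogonal as a set.

## Correlation-optimized warping

Retention-time drift between injections is corrected channel by channel.
The alignment target is the trace with the highest mean correlation to all
others. The target axis is cut into segments of `segment_length` points (the
last segment absorbs the remainder; both trace endpoints are pinned) and
each sample segment may stretch or compress by at most `slack` points, so
boundary *b* can drift up to *b* × `slack` points cumulatively. Sample
segments are linearly interpolated onto the target grid and dynamic
programming maximizes the summed per-segment Pearson correlation — a
zero-variance segment contributes 0, and score ties resolve toward the
least-deformed path. The DP is verified against exhaustive path enumeration
on small instances.

Defaults are `segment_length = 35`, `slack = 3` (mid-range of the canonical
10–50 / 1–5 grids, about one peak half-width per segment);
`optimize_warp_params()` grid-searches those ranges maximizing the mean
warped-to-target correlation, with ties to the smaller segment then smaller
slack. Since endpoints are pinned, a global shift cannot be corrected in the
first or last few segments — one reason the fingerprint window is cropped
before alignment.

## Unfolding, splitting, pretreatment

The cropped, aligned cube (1.5–6.6 min kept as a closed interval: 6121
points at 0.05 s) is unfolded wavelength-major into a samples × features
matrix — 30,605 columns for five channels, 24,484 for four. The duplex
algorithm then alternately assigns the farthest remaining Euclidean pair to
the calibration set and the next farthest to the validation set until the
validation set holds `ceiling(0.25 n)` samples (50/17 at n = 67, 176/59 at
n = 235 — the ceiling is the only rounding consistent with both splits);
every remaining sample joins the calibration set. When a single validation
slot remains, the pair member farther from the current validation set is
taken. Ties anywhere resolve to the smallest row-index pair, making the
split deterministic.

Row SNV (population sd), Savitzky–Golay derivatives (applied per wavelength
block with respect to time, default window 15 and polynomial order 2 — the
chemometric standard, and polynomial-exact so tests can use analytic
derivatives) and training-fitted autoscaling are available but **off by
default**: evaluating them showed no improvement over warping alone, so the
default pipeline applies no pretreatment after alignment.

## PLS-DA

Class membership is coded literally — a single response column with codes 1
(contains the target) and 2 (blank) for binary models; 0/1 indicator columns
per class for multiclass. Predictors and responses are mean-centered and
latent variables extracted by NIPALS with deflation (tolerance 1e-12, at
most 500 iterations per factor; with a single response column the first pass
is exact). At full rank the fit equals ordinary least squares, which is the
oracle used in the tests. The factor count is chosen by stratified 10-fold
cross-validation over 1–30 latent variables, pooling all held-out
predictions into one ccr% per factor count and taking the maximum (ties to
the fewest factors). Folds are seeded and label-stratified by round-robin
dealing; the published procedure does not state its fold construction.

Decisions: binary predictions classify as the target class when the
predicted code falls below 1.5, the midpoint of the codes (exactly 1.5
reads blank); multiclass takes the argmax of the indicator predictions with
ties to the lowest class.

## Numerical choices and degenerate inputs

* Time stamps are stored in minutes; the cube reader requires a complete
  wavelength × time grid per sample and rejects duplicates or gaps with the
  offending sample named. COW assumes index-equispaced traces.
* Zero-variance rows (SNV), columns (autoscaling), channels (correlation
  map) and segments (COW) each have a defined contract — error, flag-and-
  scale-by-1, flag-and-exclude, and score-0 respectively.
* All randomness flows from explicit integer seeds; a fixed seed makes
  simulated studies, folds and hence whole pipelines bit-reproducible.

## Limitations

* **Blank recovery under a linear simulator.** Because simulated absorbance
  is exactly linear in the spike ratio, any linear read-out makes per-matrix
  predictions affine in *r*. The least-squares optimum for codes
  {*r* = 0 → 2; *r* ∈ [1/20, 1/2] → 1} then places blanks near 1.28–1.31 —
  on the correct side of every trituration (the ordering is right, and a
  threshold calibrated on predictions would separate perfectly) but below
  the fixed 1.5 midpoint. Held-out blanks therefore read as false positives
  almost regardless of noise, amplitudes or alignment quality, which caps
  external-test ccr on simulated binary studies at roughly 70–80% — and
  reproduces, in exaggerated form, the error mode reported on real data,
  where nearly all misclassifications were blank matrices called positive.
  Real detector response is mildly non-linear, which is plausibly what keeps
  real blanks separable at the fixed midpoint. Tests that depend on blank
  verdicts therefore assert the monotone code ordering (blank codes exceed
  spiked codes), and the screening report carries the continuous codes so a
  user can see the margin, not just the verdict.
* **Pinned COW endpoints** leave residual misalignment near the window
  edges for global shifts.
* The multiclass model assigns exactly one class per sample, so co-spiked
  mixtures are attributed to a single plant; the independent binary verdicts
  are the screening tool for multi-plant detection.

## Problem sizes used by the test suite

Module tests run on reduced grids (21 channels, 0.01 min sampling) to keep
the suite fast; the end-to-end performance checks run the full study
conditions — 201-channel reference records, five-channel study cubes at
9601 time points, 6121-point fingerprints — with ten seeds per stochastic
check, about 15 s per simulated study end to end.
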