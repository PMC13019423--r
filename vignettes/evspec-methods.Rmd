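---
title: "Chemometric workflow for AFM-IR spectra of extracellular vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric workflow for AFM-IR spectra of extracellular vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evspec)
```

## The problem

Extracellular vesicles (EVs) isolated from blood by different methods —
size-exclusion chromatography (SEC), polymer precipitation (TEIR), and
differential ultracentrifugation (UC) — carry different residual protein
coronas and suffer different structural damage, and those differences show
up in their mid-infrared spectra. AFM-IR nanospectroscopy measures IR
absorption of individual particles over 950–1920 cm⁻¹, giving tens of
spectra per isolation method. This package implements the chemometric chain
that turns such spectra into statements about isolation-method effects:
outlier screening, baseline correction and normalisation, PCA and
hierarchical clustering, PLS-DA with permutation testing and VIP scoring,
pseudo-Voigt deconvolution of the albumin corona, and resampling-based
sample-size diagnostics.

Because no real spectra ship with the package, a calibrated synthetic
generator stands in for the instrument. Every stage is exercised and tested
against it, and the acceptance script recomputes the workflow's headline
numbers from it end to end.

## The synthetic generator

Each group's template is a sum of pseudo-Voigt bands

$$ I(\tilde\nu) = A\,[\eta\,L(\tilde\nu) + (1-\eta)\,G(\tilde\nu)], $$

with one band per AFM-IR entry of the packaged band-assignment table for
that isolation method (range entries at their midpoint; default FWHM
18 cm⁻¹, η = 0.5, so neighbouring bands overlap as in real bio-IR spectra).
A generated particle spectrum is

* its group template with per-band multiplicative log-normal amplitude
  jitter (CV 0.35 for TEIR and SEC, 0.50 for UC, reflecting the stronger
  heterogeneity of UC particles),
* plus an albumin corona: a per-particle fraction (Gaussian with group
  means 0.22/0.30/0.14 for TEIR/UC/SEC, SD 0.12, truncated to [0, 0.95])
  times a four-band albumin model dominated by Amide I (1650 cm⁻¹) and
  Amide II (1550 cm⁻¹),
* plus a random cubic baseline (centred uniform coefficients, scale 0.25
  intensity units on a [−1, 1]-rescaled axis),
* plus i.i.d. Gaussian noise (SD 0.40 intensity units against peak heights
  of roughly 0.3–2.6).

The between-group contrast is deliberately concentrated where the real
methods separate: group-specific amplitude multipliers at the O–P–O
symmetric phosphate stretch (977/978/982 cm⁻¹; 0.8/1.45/2.2 for
TEIR/UC/SEC) and at the glycosidic-linkage band (1035/1038 cm⁻¹;
2.05/1.3/0.65). Smaller structural differences (bands present in only some
methods' table columns, method-specific positions) remain, as they do in
real data.

No band widths, noise levels or per-band intensities are reported for the
real measurements, so all generator magnitudes are package choices. They
were calibrated once, jointly, so that the full pipeline on the frozen
default profile (40 particles per group, seed 20260917) reproduces the
workflow's reference behaviour: leave-one-out PLS-DA accuracy ≈ 0.98 (≥ 0.93),
PC1–PC2 nearest-centroid discrimination ≈ 0.98 (> 0.90), a three-cluster
dendrogram with one method per cluster (purity ≈ 0.95), and permutation
power > 80% at 30 particles per group. The calibration is frozen in
`generator_config()` and not revisited.

One consequence of that joint calibration is worth stating: an effect
strong enough to give ≥ 93% accuracy and ≥ 0.9 cluster purity at n = 40 is
already detectable at n = 10, so the resampling stability curve is nearly
flat and "stabilises" at the smallest n probed, where real data would typically
stabilise later. The stability diagnostic still behaves correctly — it
is the synthetic effect that is easier than nature's.

What the generator does **not** emulate: photothermal tip–sample mechanics,
wavenumber-dependent noise, instrument drift between sessions, PBS crystal
artefacts, or correlated (non-diagonal) within-band noise. Passing tests on
synthetic data therefore validate the statistics, not the instrument
physics.

## Preprocessing

Baseline correction is the iterative modified polyfit of Lieber and
Mahadevan-Jansen: fit a polynomial (default order 5), clamp the working
spectrum down to the fit wherever it exceeds it, and repeat until the fit
moves less than `tol` (default `1e-6 * max|I|`, cap 100 iterations). Order
5 removes the generator's cubic drift with margin while not swallowing the
broad Amide bands. Two numerical notes: the converged baseline can sit
slightly *above* the raw trace at isolated points (polynomial oscillation
between clamped regions), and on very wide windows the cumulative clamping
ratchets the baseline a few percent below the true background, inflating
integrated band intensities; both are properties of the published method,
not of this implementation.

Normalisation divides each spectrum by the sum of its absolute intensities
— absolute values keep the normaliser positive after baseline correction.
Mean-centering is applied inside PCA/PLS, never persisted.

Stage order is deliberate: outlier QC runs on mean-centered **raw**
spectra, and only the survivors are baseline-corrected and normalised.
Running QC before preprocessing is unusual, but it is the order
`run_pipeline()` implements, so artefactual particles cannot distort the
baseline statistics of the kept set.

## Outlier screening

A PCA model with the fewest components explaining 90% of variance (cap 10)
yields per-particle Hotelling T² (score-space distance) and Q residuals
(off-model distance). Both are divided by their 95% limits — T² by
`A(n−1)/(n−A) · F₀.₉₅(A, n−A)`, Q by the Jackson–Mudholkar approximation
from the discarded eigenvalues — so 1 is the decision boundary on both
axes, and a particle is flagged when **either** reduced statistic exceeds 1
(the union rule; intersection is available). The confidence level, variance
target and rule are all exposed as arguments, since none of them has a
canonical value.
On in-model Gaussian data each statistic flags ≈ 5% by design; the test
suite checks this by simulation.

## PLS-DA

The supervised engine is NIPALS PLS2 regression of one-hot class membership
on the spectra, deflating X only. The weight vector of each component is
computed at the NIPALS fixed point — the dominant left singular vector of
`Xᵀ Y`, obtained from the g×g eigenproblem — which is the exact limit of
the classical power iteration, deterministic, and fast enough to re-run
thousands of times inside permutation loops (the core is C++). Class order
is first-appearance order; predicted class is the argmax of the continuous
prediction, ties broken toward the earlier class.

Component count is chosen by leave-one-out cross-validation: the smallest A
maximising LOO accuracy (parsimony tie-break), with Q² = 1 − PRESS/TSS
reported alongside. The permutation test shuffles labels `n_perm` times
(default 999), **re-selects A by LOO within each permutation** — the
expensive but selection-bias-free variant — and reports
`p = (1 + #{perm ≥ observed}) / (1 + n_perm)`, so p can never be zero and
its floor is 1/(n_perm+1). Under the null generator the rejection rate at
α = 0.05 sits near α (slightly conservative, as the discrete add-one
correction implies); the acceptance suite verifies this over 200 seeded
replicates.

Feature relevance comes in two flavours: VIP scores
`VIP_j = sqrt(p Σ_a ssy_a w_{ja}² / Σ_a ssy_a)` (squared scores average to
1 by construction), and coefficient importance — per-class squared
regression coefficients divided by A, averaged over classes. For the heavy
resampling loops the spectra are first rotated onto an orthonormal basis of
their row space (p → ≤ n−1 dimensions); PLS predictions are exactly
invariant to this rotation, so LOO accuracies and permutation p-values are
unchanged while the loops run an order of magnitude faster.

## Albumin deconvolution

The albumin reference spectrum is fitted as a sum of pseudo-Voigt bands by
bounded Levenberg–Marquardt (centres within ±10 cm⁻¹ of initialisation,
FWHM > 0, η ∈ [0,1], amplitudes ≥ 0; the fit never returns a worse residual
than its start). Projection into an EV spectrum holds all shapes fixed and
solves nonnegative least squares for per-band amplitude multipliers
(`scale_mode = "global"` forces one shared multiplier); the EV estimate is
the sample minus the scaled albumin part, an identity that holds pointwise.

Per-band rescaling alone is not identifiable when albumin bands overlap the
EV's own protein bands — the projection soaks up genuine EV Amide
intensity. The package therefore lets the projection include **nuisance EV
bands** (by default, the assignment-table AFM-IR positions for the sample's
isolation method) as additional nonnegative regressors; only the
albumin-shaped part of the fit is subtracted. With the nuisance dictionary
the recovery on synthetic mixtures is exact in the noiseless limit and
within a few percent under realistic noise, and the estimated albumin share
is monotone in the true mixing fraction. On real spectra the dictionary is
approximate; the subtraction should then be read as "albumin-shaped
intensity at the reference band positions", which is also the honest
reading of any reference-based subtraction. Deconvolution operates on
group-average spectra by default, with per-spectrum use available.

## Sample-size diagnostics

`stability_curve()` draws `reps` fresh datasets per n (or subsamples a real
set without replacement), runs preprocessing and LOO PLS-DA, and reports
mean ± SD accuracy per n plus the smallest n within 0.02 of the largest-n
mean ("stabilised"; the threshold is a package choice, as no quantitative
rule defines “stabilised” in general). `empirical_power()` is the
fraction of replicates whose permutation p falls below α. Power at zero
effect equals α within Monte-Carlo error — the calibration anchor of the
whole permutation machinery — and is tested as such. Defaults (reps = 50,
n_perm = 199 inside power loops versus 999 for one-shot analyses, grid
{10, 20, 30, 40}) keep a full power analysis at desk scale — minutes, not
hours; all are overridable.

## Problem sizes used by the packaged checks

The acceptance checks run the frozen profile (3 × 40 spectra, 486
wavenumbers), a 50-replicate power estimate at n = 30 with 199
permutations, a 50-replicate stability curve over {10, 20, 30, 40}, and a
200-replicate null calibration at n = 15 per group with 199 permutations —
sizes chosen as the smallest at which the Monte-Carlo error is comfortably
inside each check's margin (for the null calibration, n = 15 also keeps
the discrete accuracy statistic fine-grained enough that ties do not make
the permutation test over-conservative).

## Known limitations

* The generator's calibration is a point in a large space of plausible
  AFM-IR data; conclusions about *method* behaviour (accuracy, power) are
  conditional on it.
* "Discrimination %" for a PCA score plane is operationalised as
  leave-one-out nearest-centroid accuracy — simple, deterministic, and
  monotone in class separation — because no operational definition is
  stated for the original figure.
* The dendrogram is built on preprocessed spectra with Ward linkage on
  Euclidean distances by default (raw spectra or PC scores are equally
  valid choices and selectable).
* JCAMP-DX and instrument-native file formats are not read; spectra move
  through the package as delimited text.
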