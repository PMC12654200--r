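---
title: "Methods: FTIR fingerprinting of kidney perfusion fluids"
author: "perfusir"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`perfusir` implements a complete desk-scale analysis pipeline for
mid-infrared absorbance spectra of static cold-storage perfusion fluid from
kidney allografts, aimed at discriminating donors after circulatory death
(DCD) from donors after brain death (DBD). The pipeline covers spectral
quality control, preprocessing, filter-based feature selection, donor-level
leave-one-out cross-validation (LOOCV) of two classifiers with exact
small-sample statistics, unsupervised structure, and generalized
two-dimensional correlation spectroscopy (2D-COS). Because no real cohort is
distributed with the package, a synthetic-cohort generator with fully
recorded ground truth stands in for the data; it is first-class, tested
code, and every downstream stage is validated against it.

# Data model

A spectrum is an absorbance trace on a strictly increasing wavenumber axis
(cm^-1) with donor, replicate and group metadata. A `spectra_set` collects
spectra on one shared axis; it is the currency of every stage. Four fixed
analysis windows are used throughout: the fingerprint region 900–1800
cm^-1, Amide I 1600–1700 cm^-1, and two off-band noise windows, 1800–1900
cm^-1 with a 2000–2200 cm^-1 fallback. Window bounds are closed on both
ends. Technical replicates are averaged per donor *before* any supervised
or unsupervised analysis, so replicate correlation can never leak across
cross-validation folds.

# Synthetic cohorts

`generate_cohort()` draws, per donor: band amplitudes (group mean ×
lognormal with configurable coefficient of variation), a low-order
polynomial baseline, and a lognormal pathlength scale; per replicate it adds
i.i.d. Gaussian noise and a Poisson number of single-grid-point spikes of
fixed magnitude and random sign. Bands are Gaussian
(`A exp(-4 ln 2 (v - c)^2 / w^2)`, peak height `A`, FWHM `w`) — the simplest
shape adequate for pipeline testing.

Default conditions: a 400–4000 cm^-1 grid at 2 cm^-1 spacing, 5 DCD + 5 DBD
donors, 3 technical replicates (a free choice; typical for HTS transmission
plates). Discriminant bands sit at 1202, 1342 and 1413 cm^-1 (fingerprint)
and 1673 cm^-1 (Amide I) with DCD amplitudes elevated by 0.05 absorbance —
25× the default replicate noise SD of 0.002 — over a background of shared
protein/lipid/carbohydrate bands dominated by Amide I at 1650 cm^-1.
Between-donor amplitude CVs are 5–8%, pathlength CV 3%, spike rate 1 per
spectrum at 0.05 absorbance. These are realistic magnitudes for dried-film
biofluid FTIR; they produce cohorts that full-spectrum pipelines separate
perfectly while QC metrics stay balanced between groups.

What the generator does **not** emulate: water-vapor rotational structure,
CO2 bands, Mie scattering, film-thickness interference, instrument drift
between plates. Passing tests on synthetic cohorts therefore demonstrate
correctness of the algorithms and the leakage discipline, not clinical
performance on real effluent.

# Quality control

Four metrics per donor-level spectrum:

* **Amide I SNR** — maximum rubber-band-corrected absorbance in 1600–1700
  divided by the sample SD of the corrected absorbance in the primary
  off-band window. The hull is computed on the full spectrum because the
  noise window lies outside Amide I. A window is usable when it holds at
  least 10 grid points; otherwise the fallback window is used, and as a
  last resort the SD of the whole corrected spectrum. Exact zero noise is
  an error (it signals a degenerate, noise-free input).
* **Spike count** — robust z-scores of the first differences within the
  fingerprint window, `z = (d - median d) / (1.4826 MAD d)`; points with
  |z| > 6 are flagged. The default counts flagged points; an option counts
  maximal runs instead, which matches one count per injected single-point
  spike (each spike produces an adjacent +/- difference pair). The 1.4826
  factor makes the MAD SD-consistent. MAD = 0 returns 0 by convention. A
  caveat worth knowing: any sufficiently narrow *smooth* band on a flat
  window is also flagged at its flanks — the detector is a difference
  detector, not a shape classifier.
* **Cosine shape coherence** — cosine between each vector-normalized
  fingerprint spectrum and the vector-normalized pointwise cohort median.
* **Baseline area fraction** — trapezoidal area under the rubber-band
  baseline over the fingerprint window divided by the raw area, in percent.

Group differences are assessed with the exact Mann-Whitney machinery below.
All four metrics are invariant to uniform rescaling of a spectrum.

# Preprocessing

* **Rubber-band baseline correction**: subtract the lower convex hull of
  the (wavenumber, absorbance) point set, linearly interpolated between
  hull vertices. Idempotent; validated against an O(n^2)-per-point convex
  minorant oracle.
* **Savitzky-Golay derivatives**: second-order polynomial, 15-point window,
  first or second derivative, scaled by the grid spacing so results are
  true d/dv units. Edges are truncated, never padded: 7 points per side are
  dropped, and windows are extracted with a 7-point margin so the
  derivative still covers the full region. The filter is exact on
  quadratics and is tested against an independent per-window least-squares
  fit.
* **Vector normalization**: plain unit Euclidean norm over the current
  window (region-local, i.e. applied after windowing); an optional
  mean-center-first variant exists for comparability with vendor
  conventions.

The six canonical pipelines per region are BC; VN; d1; d1 + VN; d2; and d2
with downstream FCBF. Amide I band-narrowing deconvolution is deliberately
not implemented: no defensible parameter set exists for it, and derivative
sharpening covers the same analytical need.

# Feature selection (FCBF)

The Fast Correlation-Based Filter is implemented from scratch on
symmetrical uncertainty, `SU(X, Y) = 2 I(X;Y) / (H(X) + H(Y))` with base-2
entropies of discretized variables. Features are ranked by SU with the
class (ties broken by ascending wavenumber), features at or below the
`delta` threshold (default 0) are dropped, and the ranked list is walked
keeping the head and removing every later feature that an already-kept
feature predicts at least as well as the class does
(`SU(kept, f) >= SU(f, class)`).

The default discretizer is a median split: at ten donors the Fayyad-Irani
MDL criterion (also provided) rejects cuts for all but perfectly separating
features, while a median split keeps SU estimable and deterministic.
Selection runs on donor-level rows only.

**A structural caveat that matters at n = 10.** With nine training donors a
median split yields 5/4 bins, and *any* feature whose donor ordering
happens to match the class partition attains SU = 1 — the statistic
saturates. The 15-point derivative filter spreads a band's class signal
about 14 cm^-1 beyond its support, so saturated features extend well past
the band center; the ascending-wavenumber tie-break then deterministically
keeps the *lowest* saturated wavenumber, i.e. the most marginal feature on
the left frontier of the signal region, and the redundancy rule removes
everything else (a kept feature whose bins equal the class predicts every
feature at least as well as the class does). Consequences, all verified
empirically on synthetic cohorts: per-fold selections land 8–30 cm^-1 below
a band center rather than at it; occasionally a chance-saturated background
feature wins (the probability of a random ordering matching the class
partition is 1/126 per effectively independent feature pattern); and LOOCV
accuracy through FCBF is markedly less stable than through the
full-spectrum pipelines. At twenty donors chance saturation is negligible
(2/184756) and selection reliably stays within the derivative reach of the
injected bands — the instability is a small-sample property of the method,
not an implementation artifact. This is the package's concrete restatement
of the usual warning against over-reading perfect LOOCV results at n = 10.

# Classification and evaluation

Donor-level LOOCV with two models:

* **SVM** (RBF default, C = 1, kernel width `1/(p · var)` from the
  training-fold feature matrix, features z-scored per fold with training
  statistics). The held-out donor is scored by the signed decision value,
  oriented so the positive class (default DCD) is positive.
* **Gaussian naive Bayes** with a relative variance floor of 1e-9 of the
  pooled feature variance; the score is the posterior probability of the
  positive class. A hand-rolled fit is used because the evaluation needs
  explicit control of the variance floor and of score orientation.

Feature selection, when a pipeline requests it, defaults to per-fold
(leakage-safe); a global mode reproduces the optimistic single-selection
workflow and is provided for comparison. Decision thresholds are fixed (0
for SVM, 0.5 for NB) — ten donors cannot support threshold calibration.
Reported per cell: rank-based AUC (ties 0.5, *never* flipped, so an
inverted score orientation is visible as AUC < 0.5), accuracy with the
exact Clopper-Pearson interval (`qbeta(alpha/2, k, n-k+1)` to
`qbeta(1-alpha/2, k+1, n-k)`), sensitivity, specificity, confusion counts,
per-fold scores and selected wavenumbers.

# Exact small-sample statistics

* Mann-Whitney U as the tie-aware pair count (0.5 per tie); the two-sided
  p-value enumerates all `choose(n1+n2, n1)` group assignments of the
  pooled observed values and doubles the smaller tail with a clamp at 1.
  Enumeration is limited to n1 + n2 <= 20. For equal group sizes the
  complement map guarantees a symmetric null even under ties; for unequal
  sizes with ties symmetry can fail, which is a property of the statistic,
  not a bug.
* Rank-biserial effect size `r = 1 - 2U/(n1 n2)`.
* Fisher's exact test (two-sided, point-probability rule) and the Pearson
  chi-square without continuity correction for 2x2 tables.

# Unsupervised structure

Cosine distance matrices feed (a) metric MDS — classical scaling as the
initialization, then SMACOF stress majorization to a 1e-9 relative
tolerance, deterministic, stress non-increasing by construction — and (b)
Ward hierarchical clustering via `ward.D2` applied to the cosine distances
as given (cosine distances are not Euclidean; the linkage is still well
defined, and this mirrors common chemometric practice). 2D-COS computes the
synchronous map as the feature covariance of mean-centered spectra and the
asynchronous map through the Hilbert-Noda matrix `N[j,k] = 1/(pi (k-j))`,
both with the 1/(m-1) normalization. A cross-sectional cohort has no
natural perturbation axis, so the sample order (group blocks, DBD first,
then donor id) is explicit, configurable, and returned with the maps.

# Orchestration and reproducibility

`run_full_experiment()` executes QC, the 2 x 6 x 2 evaluation grid and the
exploration stage; a failure in one grid cell is recorded in that cell's
row and never aborts the run. Every random draw descends from a single
integer seed; rerunning with the same seed reproduces every table
bit-for-bit. The numbered scripts under `analysis/` are thin narrative
drivers over these functions, and `scripts/acceptance.R` recomputes the
headline quantities from scratch for any seed.

Problem sizes were chosen to keep a full desk run comfortable: the default
test suite evaluates 50-seed batteries of 10-donor cohorts plus one
hundred-spectrum spike-recovery suite; a complete `run_full_experiment()`
takes a few seconds.

# Known limitations

* The generator's band model is Gaussian-only and omits atmospheric and
  scattering artifacts; QC behavior on real spectra will be harsher.
* FCBF at n = 10 selects frontier features (see above); results from the
  `d2+fcbf` cells should be read with that instability in mind.
* Amide I deconvolution is out of scope.
* The exact Mann-Whitney enumeration is deliberately capped at 20
  observations; larger cohorts need the normal approximation, which this
  package does not provide.
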