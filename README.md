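# perfusir

FTIR fingerprinting of kidney perfusion fluids: an R package for
discriminating donation-after-circulatory-death (DCD) from
donation-after-brain-death (DBD) donors from mid-infrared absorbance
spectra of static cold-storage effluent.

Kidneys from DCD and DBD donors follow different injury chronologies (warm
ischemia versus catecholamine/cytokine storm), and the preservation fluid
that bathes the organ plausibly concentrates the corresponding cell-free
chemistry. Label-free FTIR of the dried effluent is a minute-scale,
consumable-free readout of that chemistry. This package implements the full
analysis chain such a study needs, for spectroscopists and transplant
researchers who want a tested, reproducible, leakage-disciplined pipeline —
and, because raw cohorts of this kind are rarely shareable, a synthetic
cohort generator with recorded ground truth against which every stage is
validated.

## What is implemented

* **Quality control** (donor-level): Amide I signal-to-noise
  (rubber-band-corrected peak over off-band SD, with a fallback window
  ladder), spike burden via robust z-scores of first differences
  (|z| > 6 on the SD-consistent MAD scale), cosine shape coherence against
  the vector-normalized cohort median, and the baseline-to-raw area
  fraction.
* **Preprocessing**: rubber-band (lower convex hull) baseline correction,
  Savitzky–Golay derivatives (2nd-order polynomial, 15-point window, true
  d/dν units, truncated edges), vector normalization; six canonical
  pipelines per spectral region (fingerprint 900–1800 cm⁻¹, Amide I
  1600–1700 cm⁻¹).
* **Feature selection**: Fast Correlation-Based Filter from scratch on
  symmetrical uncertainty, SU(X,Y) = 2·I(X;Y)/(H(X)+H(Y)), with supervised
  discretization (median split, quantile bins, or Fayyad–Irani MDL) and
  deterministic redundancy elimination.
* **Evaluation**: donor-level LOOCV of an RBF-SVM and a Gaussian naive
  Bayes; rank-based AUC (ties 0.5, never flipped), accuracy with the exact
  Clopper–Pearson 95% CI, sensitivity, specificity, per-fold selections.
* **Exact statistics**: tie-aware Mann–Whitney U with a full-enumeration
  two-sided p, rank-biserial r = 1 − 2U/(n₁n₂), Fisher exact
  (point-probability rule) and Pearson chi-square for 2×2 tables.
* **Unsupervised structure**: cosine distances, SMACOF MDS (classical
  scaling init, monotone stress), Ward (D2) clustering, and generalized
  2D correlation spectroscopy (synchronous covariance map, asynchronous
  Hilbert–Noda map).

## Worked example

```r
library(perfusir)

cohort <- generate_cohort(synthetic_config(seed = 20260929))
donors <- aggregate_replicates(cohort$set)

qc_group_compare(qc_table(donors))[, c("metric", "u", "p_value", "rank_biserial_r")]
#>                   metric  u p_value rank_biserial_r
#> 1            snr_amide_i  7   0.310            0.44
#> 2            spike_count 15   0.643           -0.20
#> 3              cosine_fp 10   0.690            0.20
#> 4 baseline_area_fraction 15   0.690           -0.20
```

No QC metric separates the groups (all exact p ≥ 0.31): technical quality
is balanced, so any classification signal is not an acquisition artifact.

```r
pl <- pipeline_from_slug("fingerprint", "d2")
ev <- loocv_evaluate(prepare_region(donors, pl), pl,
                     eval_config(model = "naive_bayes"))
ev
#> <loocv_eval> 2nd derivative | AUC 1.00 | accuracy 1.00 (0.69-1.00) | sens 1.00 | spec 1.00
```

The second-derivative fingerprint pipeline separates the cohort perfectly
under donor-level LOOCV; with n = 10 the exact binomial CI on a 10/10
accuracy still reaches down to 0.69, which is the honest statement of what
ten donors can show. The unsupervised view agrees: after the same
preprocessing, mean within-group cosine distance is 0.0031 versus 0.0333
between groups, and the 2-cluster Ward cut reproduces the donor types
exactly.

The numbered scripts in `analysis/` run the whole study in order —
`01_simulate.R` (cohort + ground truth), `02_qc.R`, `03_classify.R` (the
2 regions × 6 pipelines × 2 models LOOCV grid), `04_explore.R` — each
writing its tables under `results/`.

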