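---
title: "Voxel-wise modelling of glioma progression from multiparametric maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise modelling of glioma progression from multiparametric maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`voxelprog` treats prediction of tumour progression as a voxel-level binary
regression problem. For each patient, co-registered parametric maps —
CT-perfusion blood flow (BF, mL/min per 100 g), blood volume (BV, mL/100 g)
and permeability–surface area product (PS, mL/min per 100 g), plus the
FDG-PET standard uptake value (SUV, body-surface-area normalised) and the
derived metabolism-to-flow ratio SUV:BF — are sampled inside an analysis
mask, and each voxel carries three binary statuses: membership of the
pre-radiotherapy gross tumour, of the near-end-of-radiotherapy enhancing
lesion, and of the progressive tumour contoured on follow-up MR (the
outcome). Voxels from all patients are pooled into a single logistic
regression

$$\operatorname{logit} P(\text{progression}) = \beta_0 + \beta^\top x,$$

fitted by iteratively reweighted least squares in raw physiological units.
Pooling (no per-patient random effects) is a deliberate design choice: it
mirrors the single pooled fit behind the published per-unit odds ratios and
the single quoted degrees of freedom, and it is what makes the per-unit
odds-ratio interpretation (`exp(beta)` per mL/min/100 g, etc.) direct. The
cost is that standard errors ignore within-patient correlation and should be
read as descriptive of the pooled sample rather than as population
inference; cross-validated discrimination, not the pooled SEs, is the
package's primary evidence measure.

Reported per term: the coefficient, its SE, the odds ratio `exp(beta)` with
Wald 95% CI `exp(beta ± 1.959964·se)` (Wald rather than profile intervals —
at 10^5 pooled voxels the likelihood is effectively quadratic and published
intervals of this kind are symmetric on the log scale), and a probability
column `100·expit(beta0 + beta)` — the predicted progression probability at
one unit of the covariate with the others at zero, the convention that
reproduces published tables of this analysis; `scaled_odds()` provides the
same quantities for a rescaled increment (e.g. per 0.01 of SUV:BF, whose
per-unit odds ratio is not interpretable at its natural 0.01–0.1 scale).
The degrees of freedom follow the `n − p` convention with the intercept
counted.

## Preprocessing contracts

* **Bounding box.** A rectangular in-plane margin of 2 cm (default) beyond
  the extent of the union of gross and progressive tumour, computed per
  section and never propagated across the 5-mm sections (the perfusion
  acquisition covers only eight sections; per-section treatment matches how
  such maps are read). The margin is converted to voxels with `ceiling()`,
  so it is never under the requested distance. A 3-D single-box variant is
  available (`per_section = FALSE`).
* **Exclusions.** Major vessels, surgical cavities and ventricles enter as a
  binary exclusion mask; `analysis = bounding_box & !exclusion`. The package
  takes the exclusion mask as input and does not attempt to segment these
  structures.
* **Resampling.** Continuous maps bilinear, masks nearest-neighbour (labels
  stay binary); in-plane spacing metadata is rescaled so the field of view
  is preserved.
* **Missing covariates.** SUV:BF is undefined where BF falls below a floor
  (default 1 mL/min per 100 g — below CT-perfusion noise); such voxels are
  dropped from the table and counted, never imputed: imputation would invent
  tissue physiology.
* **Progression site.** A progressive lesion is in-field when every voxel
  lies within 2 cm (in-plane Euclidean distance) of a gross-tumour voxel,
  out-of-field when none does, otherwise both.

## Cross-validation and evaluation

Leave-one-patient-out: each fold refits the pooled regression without the
held-out patient and applies the fitted equation to that patient's voxels,
yielding a probability map that never saw its own labels. Discrimination is
evaluated per held-out patient — ROC over all distinct predicted
probabilities, trapezoidal AUC (equivalently the tie-corrected Mann–Whitney
concordance), and the Youden-optimal threshold maximising
sensitivity + specificity − 1. Scanning the observed probabilities is a
superset of any fixed 0–100% grid, so no operating point can be missed; ties
in J are broken toward the lowest threshold, favouring sensitivity — the
conservative choice for a planning application where missing progressive
tissue is costlier than over-covering. Cohort summaries are unweighted
mean ± SD across patients, which is the only level at which an SD over the
cohort exists.

Model comparison is gatekept: a Friedman test (tie-corrected, within-patient
ranks) across all models first; pairwise exact Wilcoxon signed-rank tests of
per-patient AUCs against the anatomical baselines only if the Friedman test
rejects at 0.05. Pairwise p-values are left uncorrected (flagged in the
output) — matching standard practice for this gatekept design at n = 10.
The Wilcoxon test is exact by enumeration of the positive-rank-sum
distribution (computed by convolution over the tied average ranks) for up to
15 non-zero differences — at cohort sizes around 10 the normal approximation
is poor — and tie-corrected normal above that; zero differences are dropped,
the standard convention.

## The synthetic cohort

The generator emulates the *structure* of the study data, not its exact
distributions (which are unpublished): per patient, a brain of grey/white
ellipses, a gross-tumour ellipsoid, an offset progressive-region ellipsoid,
an enhancing lesion overlapping the gross tumour, ventricle/vessel/cavity
exclusions; class-mean covariate fields plus smooth within-class
heterogeneity (Gaussian field, 6-mm FWHM) form the *true* maps; observed
maps add voxel noise and 2-mm smoothing, clamped non-negative. Default
class means (BF 50/25/40/32, BV 4/2/3.5/3, PS 0.5/0.3/3/6, SUV
1.6/0.8/2.2/2.4 for grey/white/gross/progressive) are field-plausible
values chosen once; only their contrasts and directions matter for testing.

Progression labels are Bernoulli draws from the ground-truth model applied
to the **true** fields, with default coefficients
(−2.2, BF −0.02, BV −0.15, PS +0.9, SUV −0.9, SUV:BF +8) — directions
matching the published multivariate effects, magnitudes giving class-level
progression probabilities of roughly 1% (grey), 4% (white), 9% (gross) and
64% (progressive region). The contoured progressive-tumour *mask* is the
morphological closing (2-mm disc) of the draws within the dilated
progressive region — the contiguous lesion a radiologist would contour —
while the raw draws are retained in the `truth` component. Two consequences
are deliberate:

* parameter-recovery experiments fit the true fields against the raw draws,
  for which the logistic model is exactly the data-generating process, so
  Wald coverage can be tested honestly;
* pipeline runs on the observed maps against the contoured mask include
  covariate noise and contouring distortion, so their coefficients are
  attenuated relative to truth — as with real data. They are therefore
  validated by discrimination and direction, not by coverage.

Per-patient sub-seeds are drawn deterministically from the master seed, so a
cohort is bit-reproducible from `(config, seed)` and any patient can be
regenerated standalone.

What the generator does **not** emulate: registration error, partial-volume
effects at tissue boundaries, deconvolution artefacts in the perfusion maps,
non-ellipsoidal lesion shapes, and realistic spatial autocorrelation of the
measurement noise. Passing tests on synthetic cohorts therefore demonstrate
correctness of the *pipeline* under a known model, and say nothing about
clinical effect sizes; the synthetic contrasts are cleaner than clinical
data, and cross-validated AUCs near 0.95 here should not be read against the
published 0.72–0.77.

## Numerical choices

* IRLS convergence at `max |Δβ| < 1e−8` or 100 iterations; weights floored
  at 1e−10; rank-deficient design matrices rejected with the dependent
  columns named.
* Quasi-separation is detected scale-invariantly (a slope exceeding 30
  log-odds per covariate SD, or a mean linear predictor beyond ±30) and
  surfaced as a warning plus `converged = FALSE`, never silently.
* Probability maps are clipped to [0, 1] only for sub-1e−3 float
  excursions (logged); larger violations and NaN inside the analysis mask
  are errors.
* Voxel tables are written CSV at shortest-round-trip float precision, with
  0-based (row, col, section) coordinates, stated in the fixed header.

## Problem sizes used by the test-suite experiments

Unit tests run on 64–96 voxel grids with 2–6 patients (seconds). The
parameter-recovery experiment uses 20 replicate cohorts at the default
study conditions (10 patients, 170 × 170 × 8, ~10⁵ pooled analysis voxels),
where every default coefficient — including the weak BF effect, whose
|β|/SE is only ≈ 3 at that size — is powered for sign recovery; the
determinism check runs the full default pipeline twice.

## Known limitations

* Pooled fits ignore within-patient correlation (see above); no
  mixed-effects or spatially correlated error models.
* No image registration: inputs are assumed co-registered, as produced by
  external rigid registration.
* No DICOM ingestion or CT-perfusion deconvolution; maps enter as NIfTI.
* The univariate gross-tumour / enhancing-lesion probability figures of the
  published analysis imply unprinted intercepts and cannot be reconstructed
  from the printed table; the package reproduces the multivariate reporting
  identities instead.
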